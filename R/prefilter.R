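#' Panel heritability by one-way ANOVA
#'
#' For each transcript, heritability is the coefficient of determination
#' R^2 = SS_between / SS_total from a one-way ANOVA of per-animal
#' expression values with strain as the only predictor. The estimator is
#' invariant to affine transforms of the expression scale. Transcripts
#' with zero total sum of squares are flagged undefined.
#'
#' @param expr matrix transcripts x libraries (individual animals)
#' @param strains strain label per library
#' @return data.frame: transcript_id, r_squared, n_strains, df_residual,
#'   undefined
#' @export
heritability <- function(expr, strains) {
  expr <- as.matrix(expr)
  strains <- as.character(strains)
  if (length(strains) != ncol(expr))
    stop("one strain label per library required")
  g <- factor(strains)
  k <- nlevels(g)
  n <- ncol(expr)
  if (k < 2L || n < k + 1L)
    stop("need >= 2 strains and more animals than strains")
  gm <- rowMeans(expr)
  sst <- rowSums((expr - gm)^2)
  means <- t(rowsum(t(expr), g) / as.vector(table(g)))   # tx x strain
  ssb <- rowSums(sweep(means, 1L, gm)^2 %*% diag(as.vector(table(g))))
  undefined <- sst == 0
  r2 <- ifelse(undefined, NA_real_, pmin(pmax(ssb / sst, 0), 1))
  data.frame(transcript_id = rownames(expr), r_squared = r2,
             n_strains = k, df_residual = n - k,
             undefined = undefined,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dominant-isoform filter
#'
#' Per gene, keeps the `k` transcripts with the highest mean TPM across
#' the designated libraries. Ties at the cutoff break by lexicographic
#' transcript id, so the result is independent of input order.
#'
#' @param counts estimated counts, transcripts x libraries
#' @param ann a `txome` covering the count rows
#' @param k isoforms retained per gene (default 3)
#' @param libraries libraries used for the mean TPM (default all columns)
#' @return character vector of retained transcript ids, with attribute
#'   `mean_tpm`
#' @export
top_k_isoforms <- function(counts, ann, k = 3, libraries = NULL) {
  stopifnot(inherits(ann, "txome"))
  counts <- as.matrix(counts)
  if (is.null(libraries)) libraries <- colnames(counts)
  lens <- setNames(ann$transcripts$length, ann$transcripts$transcript_id)
  tpm_mat <- tpm(counts[, libraries, drop = FALSE], lens[rownames(counts)])
  mean_tpm <- rowMeans(tpm_mat)
  gene <- ann$transcripts[rownames(counts), "gene_id"]
  ord <- order(gene, -mean_tpm, rownames(counts))
  ids <- rownames(counts)[ord]
  gs <- gene[ord]
  rank_in_gene <- stats::ave(seq_along(ids), gs, FUN = seq_along)
  keep <- ids[rank_in_gene <= k]
  keep <- keep[order(match(keep, rownames(counts)))]
  attr(keep, "mean_tpm") <- mean_tpm
  keep
}

#' Transcript-reduction cascade before network and association analyses
#'
#' Ordered steps: (1) keep the top-`k` expressed isoforms per gene by mean
#' TPM; (2) drop transcripts whose heritability is at or below the median
#' heritability of the current (post step 1) set; (3) drop transcripts
#' that cannot be associated with a reference gene through a shared splice
#' junction. A ledger records totals and per-source counts at each step,
#' and the realized median heritability.
#'
#' @param counts estimated counts, transcripts x libraries
#' @param herit data.frame from [heritability()]
#' @param ann a `txome` covering the counts
#' @param reference a `txome` of reference transcripts for the gene
#'   association step
#' @param k dominant isoforms per gene (default 3)
#' @param libraries libraries for the mean TPM (default all)
#' @param single_exon_overlap passed to [shares_splice_junction()]
#' @return list: `retained` ids, `ledger`, `median_r_squared`,
#'   `gene_association` (named vector)
#' @export
apply_prefilter <- function(counts, herit, ann, reference, k = 3,
                            libraries = NULL, single_exon_overlap = FALSE) {
  stopifnot(inherits(ann, "txome"))
  ids0 <- rownames(counts)
  if (!all(ids0 %in% herit$transcript_id))
    stop("heritability missing for some transcripts")
  ledger <- ledger_row(ann, ids0, "input")

  ids1 <- top_k_isoforms(counts, ann, k = k, libraries = libraries)
  ledger <- rbind(ledger, ledger_row(ann, ids1, "top_isoforms",
                                     sprintf("k=%d by mean TPM", k)))

  r2 <- setNames(herit$r_squared, herit$transcript_id)[ids1]
  med <- median(r2, na.rm = TRUE)
  keep2 <- !is.na(r2) & r2 > med
  if (!any(keep2))
    warning("all transcripts at or below the median heritability; none retained")
  ids2 <- ids1[keep2]
  ledger <- rbind(ledger, ledger_row(ann, ids2, "heritability_filter",
                                     sprintf("drop r_squared <= median (%.3f)",
                                             med)))

  assoc <- shares_splice_junction(ann, reference, ids = ids2,
                                  single_exon_overlap = single_exon_overlap)
  ids3 <- ids2[!is.na(assoc)]
  ledger <- rbind(ledger, ledger_row(ann, ids3, "gene_association_filter",
                                     "shared splice junction with reference"))
  check_ledger(ledger)
  list(retained = ids3, ledger = ledger, median_r_squared = med,
       gene_association = assoc)
}
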