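#' Candidacy thresholds
#'
#' @param correlation_p_max Spearman p-value threshold for trait
#'   association (default 0.01)
#' @param qtl_genomewide_p_max genome-wide empirical p threshold for the
#'   feature's own QTL (default 0.01)
#' @param pqtl_tiers named alpha levels qualifying a phenotype QTL for
#'   overlap (default significant = 0.05, suggestive = 0.63)
#' @export
candidate_criteria <- function(correlation_p_max = 0.01,
                               qtl_genomewide_p_max = 0.01,
                               pqtl_tiers = c(significant = 0.05,
                                              suggestive = 0.63)) {
  stopifnot(correlation_p_max > 0, correlation_p_max < 1,
            qtl_genomewide_p_max > 0, qtl_genomewide_p_max < 1,
            all(pqtl_tiers > 0), all(pqtl_tiers < 1))
  list(correlation_p_max = correlation_p_max,
       qtl_genomewide_p_max = qtl_genomewide_p_max,
       pqtl_tiers = pqtl_tiers)
}

#' Spearman rank association
#'
#' rho on average ranks (ties allowed); two-sided p-value from the
#' t-distribution approximation with n-2 degrees of freedom. The
#' approximation is adequate at panel sizes of 20-30 strains.
#'
#' @param x,y paired strain values (>= 5 pairs)
#' @return list: `rho`, `p`, `n`
#' @export
spearman_assoc <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("need >= 5 paired strains")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

peak_in_any_pqtl_ci <- function(peak_chrom, peak_pos, pqtl_peaks, tiers) {
  if (is.null(pqtl_peaks) || !nrow(pqtl_peaks)) return(NA_character_)
  q <- pqtl_peaks[pqtl_peaks$tier %in% names(tiers), , drop = FALSE]
  hit <- q$chrom == peak_chrom & peak_pos >= q$ci_lo & peak_pos <= q$ci_hi
  if (!any(hit)) return(NA_character_)
  paste0(q$chrom[hit], ":", q$pos[hit])[1L]
}

## shared worker: apply the three criteria to a set of strain-level traits
select_candidates <- function(traits, phenotype, geno, criteria, n_perm,
                              seed, feature_kind, positions = NULL,
                              pqtl_peaks = NULL, local_window = 1e7,
                              cap = 50) {
  records <- list()
  feat_ids <- rownames(traits)
  seeds <- seeds_for(seed, length(feat_ids))
  for (i in seq_along(feat_ids)) {
    id <- feat_ids[i]
    x <- traits[id, ]
    common <- intersect(names(phenotype), colnames(traits))
    sa <- spearman_assoc(x[common], phenotype[common])
    if (is.na(sa$p) || sa$p >= criteria$correlation_p_max) next
    scan <- genome_scan(x, geno, cap = cap)
    pk <- scan_peak(scan)
    thr <- permutation_thresholds(x, geno, n_perm = n_perm,
                                  alphas = c(0.01, 0.05, 0.63),
                                  seed = seeds[i], cap = cap)
    p_gw <- empirical_p(pk$lod, thr)
    if (p_gw >= criteria$qtl_genomewide_p_max) next
    overlap <- peak_in_any_pqtl_ci(pk$chrom, pk$pos, pqtl_peaks,
                                   criteria$pqtl_tiers)
    if (is.na(overlap)) next
    ci <- bayes_credible_interval(scan, pk$chrom)
    locality <- NA_character_
    if (!is.null(positions) && id %in% rownames(positions))
      locality <- classify_eqtl(pk$chrom, pk$pos,
                                positions[id, "chrom"],
                                as.numeric(positions[id, "start"]),
                                as.numeric(positions[id, "end"]),
                                window = local_window)
    records[[id]] <- data.frame(
      feature_id = id, kind = feature_kind,
      rho = sa$rho, cor_p = sa$p, n_strains = sa$n,
      lod = pk$lod, qtl_p = p_gw,
      qtl_chrom = pk$chrom, qtl_pos = pk$pos,
      ci_lo = ci$lo, ci_hi = ci$hi,
      pqtl_overlap = overlap, locality = locality,
      stringsAsFactors = FALSE)
  }
  if (!length(records))
    return(data.frame(feature_id = character(), kind = character(),
                      rho = numeric(), cor_p = numeric(),
                      n_strains = integer(), lod = numeric(),
                      qtl_p = numeric(), qtl_chrom = character(),
                      qtl_pos = numeric(), ci_lo = numeric(),
                      ci_hi = numeric(), pqtl_overlap = character(),
                      locality = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  out <- out[order(out$cor_p), , drop = FALSE]
  out$fdr <- p.adjust(out$cor_p, method = "BH")   # informational only
  rownames(out) <- NULL
  out
}

#' Individual candidate transcripts
#'
#' A transcript qualifies when (1) its strain-mean expression is Spearman-
#' correlated with the phenotype below `correlation_p_max`; (2) its best
#' eQTL reaches genome-wide empirical significance below
#' `qtl_genomewide_p_max`; and (3) the eQTL peak marker falls inside the
#' 95% Bayesian credible interval (inclusive endpoints, same chromosome)
#' of any tier-qualifying phenotype QTL. Records are ordered by
#' correlation p-value; no multiple-testing correction is applied to the
#' criteria (an informational BH column is emitted).
#'
#' @param expr strain-mean expression, transcripts x strains
#' @param phenotype named strain means of the trait
#' @param geno `genotype_matrix` (SDP-collapsed)
#' @param ann a `txome` giving transcript positions (for local/distal)
#' @param pqtl_peaks data.frame from [qtl_peaks()] for the phenotype
#' @param criteria a [candidate_criteria()] list
#' @param n_perm permutations per transcript scan (default 1000)
#' @param seed RNG seed (per-transcript child seeds are derived)
#' @param local_window local-eQTL window in bases
#' @return data.frame of candidate records (possibly empty)
#' @export
candidate_transcripts <- function(expr, phenotype, geno, ann, pqtl_peaks,
                                  criteria = candidate_criteria(),
                                  n_perm = 1000L, seed = NULL,
                                  local_window = 1e7) {
  stopifnot(inherits(ann, "txome"))
  pos <- ann$transcripts[, c("chrom", "start", "end")]
  select_candidates(expr, phenotype, geno, criteria, n_perm, seed,
                    feature_kind = "transcript", positions = pos,
                    pqtl_peaks = pqtl_peaks, local_window = local_window)
}

#' Candidate coexpression modules
#'
#' As [candidate_transcripts()], with module eigengenes as the traits
#' (module-eigengene QTL in place of eQTL).
#'
#' @param eigengenes matrix modules x strains of eigengene values
#' @inheritParams candidate_transcripts
#' @export
candidate_modules <- function(eigengenes, phenotype, geno, pqtl_peaks,
                              criteria = candidate_criteria(),
                              n_perm = 1000L, seed = NULL) {
  select_candidates(as.matrix(eigengenes), phenotype, geno, criteria,
                    n_perm, seed, feature_kind = "module",
                    pqtl_peaks = pqtl_peaks)
}

#' Per-gene isoform context for a candidate transcript
#'
#' Sibling isoforms of the candidate's gene in the detected-above-
#' background annotation, their per-source counts, and whether the
#' candidate is the dominant isoform by mean TPM.
#'
#' @param transcript_id candidate transcript
#' @param ann the DABG `txome`
#' @param mean_tpm named vector of per-transcript mean TPM
#' @return list: `gene_id`, `n_isoforms`, `by_source` (ensembl/stringtie/
#'   aptardi counts), `source_string` ("n; e/s/a"), `dominant`
#' @export
isoform_context <- function(transcript_id, ann, mean_tpm) {
  stopifnot(inherits(ann, "txome"))
  tx <- ann$transcripts
  if (!transcript_id %in% tx$transcript_id)
    stop("transcript not in annotation: ", transcript_id)
  gene <- tx[transcript_id, "gene_id"]
  sib <- tx[tx$gene_id == gene, , drop = FALSE]
  cnt <- table(factor(sib$source, levels = TX_SOURCES))
  dom <- sib$transcript_id[order(-mean_tpm[sib$transcript_id],
                                 sib$transcript_id)][1L]
  list(gene_id = gene,
       n_isoforms = nrow(sib),
       by_source = as.integer(cnt),
       source_string = sprintf("%d; %d/%d/%d", nrow(sib),
                               cnt["ensembl"], cnt["stringtie"],
                               cnt["aptardi"]),
       dominant = dom == transcript_id)
}
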