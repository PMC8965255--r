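#' @importFrom stats cor median quantile rbinom rnbinom rnorm runif sd var
#'   p.adjust pt rmultinom aggregate setNames complete.cases
#' @importFrom utils head read.delim write.table
NULL

TX_SOURCES <- c("ensembl", "stringtie", "aptardi")

#' Construct a transcriptome annotation from an exon table
#'
#' The annotation is the package's central bookkeeping object: a set of
#' transcript models assembled from exon records, each carrying a gene id,
#' a source label (reference annotation, splice reconstruction, or
#' 3'-terminus extension), and a strand-aware 3' terminus.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` (`+`/`-`), `start`, `end` (1-based inclusive), and optionally
#'   `source` (one of `"ensembl"`, `"stringtie"`, `"aptardi"`).
#' @return An object of class `txome` with components `transcripts`
#'   (one row per transcript: id, gene, chrom, strand, source, span,
#'   exon count, spliced length, 3' terminus) and `exons` (per-transcript
#'   exon table sorted by genomic start).
#' @export
txome <- function(exons) {
  required <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols))
    stop("exon table lacks columns: ", paste(missing_cols, collapse = ", "))
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$gene_id <- as.character(exons$gene_id)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  if (!all(exons$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(exons$start > exons$end))
    stop("exon start > end")
  if (is.null(exons$source)) exons$source <- NA_character_
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  ## per-transcript validation: single chrom/strand/gene, no overlapping exons
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  tx_ids <- names(sp)
  first <- vapply(sp, `[`, integer(1), 1L)
  for (nm in tx_ids) {
    idx <- sp[[nm]]
    if (length(unique(exons$chrom[idx])) > 1L ||
        length(unique(exons$strand[idx])) > 1L ||
        length(unique(exons$gene_id[idx])) > 1L)
      stop("transcript ", nm, " has inconsistent chrom/strand/gene_id")
    if (length(idx) > 1L) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (any(s[-1L] <= e[-length(e)]))
        stop("overlapping exons within transcript ", nm)
    }
  }
  len <- vapply(sp, function(i) sum(exons$end[i] - exons$start[i] + 1L),
                numeric(1))
  n_ex <- lengths(sp)
  tx <- data.frame(
    transcript_id = tx_ids,
    gene_id = exons$gene_id[first],
    chrom = exons$chrom[first],
    strand = exons$strand[first],
    source = exons$source[first],
    start = vapply(sp, function(i) min(exons$start[i]), numeric(1)),
    end = vapply(sp, function(i) max(exons$end[i]), numeric(1)),
    n_exons = as.integer(n_ex),
    length = len,
    stringsAsFactors = FALSE
  )
  tx$terminus <- ifelse(tx$strand == "+", tx$end, tx$start)
  rownames(tx) <- tx$transcript_id
  structure(list(transcripts = tx, exons = exons), class = "txome")
}

#' @export
print.txome <- function(x, ...) {
  cat("txome:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes\n")
  print(table(source = x$transcripts$source, useNA = "ifany"))
  invisible(x)
}

#' Subset an annotation to a set of transcripts
#' @param ann a `txome`
#' @param ids transcript ids to keep
#' @export
subset_txome <- function(ann, ids) {
  stopifnot(inherits(ann, "txome"))
  ids <- intersect(ann$transcripts$transcript_id, ids)
  txome(ann$exons[ann$exons$transcript_id %in% ids,
                  c("transcript_id", "gene_id", "chrom", "strand",
                    "start", "end", "source")])
}

## Fallback source inference from id conventions: an id that is an existing
## id plus a trailing ".N" is a 3'-extension duplicate (aptardi); otherwise
## ENS* ids are reference and MSTRG* ids are splice reconstruction.
infer_source <- function(ids) {
  base <- sub("\\.[0-9]+$", "", ids)
  src <- ifelse(base != ids & base %in% ids, "aptardi",
         ifelse(grepl("^ENS", ids), "ensembl",
         ifelse(grepl("^MSTRG", ids), "stringtie", NA_character_)))
  if (anyNA(src))
    warning("could not infer source for ",
            sum(is.na(src)), " transcript id(s); left NA")
  src
}

#' Read a GTF annotation into a `txome`
#'
#' Exon features are parsed with rtracklayer. The per-transcript source
#' label is read from a GTF attribute (default `source_label`); when the
#' attribute is absent the label is inferred from id conventions (see
#' Details).
#'
#' @details Id-convention fallback: an id equal to an existing id plus a
#'   trailing `.N` is taken as a 3'-terminus extension (`aptardi`); ids
#'   starting `ENS` as reference (`ensembl`); ids starting `MSTRG` as
#'   splice reconstruction (`stringtie`).
#' @param path GTF file
#' @param source_attribute GTF attribute holding the source label
#' @return a `txome`
#' @export
parse_gtf <- function(path, source_attribute = "source_label") {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  tx_id <- S4Vectors::mcols(gr)$transcript_id
  if (is.null(tx_id) || anyNA(tx_id)) {
    ## recover line numbers of offending exon records for the error message
    lines <- readLines(path)
    bad <- which(grepl("\texon\t", lines) & !grepl("transcript_id", lines))
    stop("exon feature(s) without transcript_id at line(s): ",
         paste(head(bad, 10L), collapse = ", "))
  }
  src <- S4Vectors::mcols(gr)[[source_attribute]]
  ex <- data.frame(
    transcript_id = as.character(tx_id),
    gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(src)) {
    ex$source <- as.character(src)
  } else {
    ids <- unique(ex$transcript_id)
    ex$source <- infer_source(ids)[match(ex$transcript_id, ids)]
  }
  txome(ex)
}

#' Write a `txome` to GTF
#'
#' Exon records carry `transcript_id`, `gene_id` and a `source_label`
#' attribute so that `parse_gtf()` round-trips the model exactly.
#' @param ann a `txome`
#' @param path output file
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "txome"))
  ex <- ann$exons
  src <- ann$transcripts[ex$transcript_id, "source"]
  gr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start, ex$end), strand = ex$strand)
  S4Vectors::mcols(gr)$source <- ifelse(is.na(src), "unknown", src)
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  S4Vectors::mcols(gr)$source_label <- src
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Strand-aware 3' termini
#'
#' The 3' terminus of a transcript is the genomic coordinate of its final
#' base: the last exon's end on "+", the first exon's start on "-".
#' @param ann a `txome`
#' @param ids transcripts to report (default all)
#' @return data.frame with transcript_id, chrom, strand, terminus
#' @export
three_prime_termini <- function(ann, ids = NULL) {
  stopifnot(inherits(ann, "txome"))
  tx <- ann$transcripts
  if (!is.null(ids)) {
    missing <- setdiff(ids, tx$transcript_id)
    if (length(missing)) stop("unknown transcript(s): ",
                              paste(head(missing, 5L), collapse = ", "))
    tx <- tx[ids, , drop = FALSE]
  }
  data.frame(transcript_id = tx$transcript_id, chrom = tx$chrom,
             strand = tx$strand, terminus = tx$terminus,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Test whether two 3' termini match within a tolerance
#'
#' Chromosome and strand equality is the caller's responsibility; this is
#' the coordinate rule only. The tolerance boundary is inclusive.
#' @param a,b genomic coordinates (vectorized)
#' @param tolerance maximum absolute difference in bases (default 100)
#' @export
match_termini <- function(a, b, tolerance = 100) {
  if (tolerance < 0) stop("tolerance must be non-negative")
  abs(a - b) <= tolerance
}

#' Ledger of 3'-extension transcript/terminus pairs
#'
#' For every transcript from the 3'-terminus extension source, flags
#' whether its terminus matches (same chromosome and strand, within
#' `tolerance` bases, inclusive) the terminus of any reference or
#' splice-reconstruction transcript. Also reports the number of unique
#' termini (exact-coordinate deduplication) among the extension
#' transcripts and the mean number of transcripts per unique terminus.
#'
#' @param ann a `txome` with source labels
#' @param tolerance matching window in bases (default 100)
#' @return list with `pairs` (data.frame transcript_id, chrom, strand,
#'   terminus, matched), `n_transcripts`, `n_unique_termini`,
#'   `mean_transcripts_per_terminus`, `matched_fraction`
#' @export
terminus_pair_ledger <- function(ann, tolerance = 100) {
  stopifnot(inherits(ann, "txome"))
  tx <- ann$transcripts
  apa <- tx[!is.na(tx$source) & tx$source == "aptardi", , drop = FALSE]
  other <- tx[!is.na(tx$source) & tx$source != "aptardi", , drop = FALSE]
  matched <- logical(nrow(apa))
  if (nrow(apa) && nrow(other)) {
    key_o <- paste(other$chrom, other$strand)
    by_key <- split(other$terminus, key_o)
    key_a <- paste(apa$chrom, apa$strand)
    for (i in seq_len(nrow(apa))) {
      cand <- by_key[[key_a[i]]]
      matched[i] <- !is.null(cand) &&
        any(match_termini(apa$terminus[i], cand, tolerance))
    }
  }
  uniq <- unique(paste(apa$chrom, apa$strand, apa$terminus))
  list(
    pairs = data.frame(transcript_id = apa$transcript_id, chrom = apa$chrom,
                       strand = apa$strand, terminus = apa$terminus,
                       matched = matched, row.names = NULL,
                       stringsAsFactors = FALSE),
    n_transcripts = nrow(apa),
    n_unique_termini = length(uniq),
    mean_transcripts_per_terminus =
      if (length(uniq)) nrow(apa) / length(uniq) else NA_real_,
    matched_fraction = if (nrow(apa)) mean(matched) else NA_real_
  )
}

## junction keys of one transcript: (exon_end_i, exon_start_{i+1}) pairs,
## strand-aware via the chrom/strand prefix; exact coordinates only.
junction_keys <- function(chrom, strand, starts, ends) {
  n <- length(starts)
  if (n < 2L) return(character(0))
  paste(chrom, strand, ends[-n], starts[-1L], sep = ":")
}

txome_junctions <- function(ann) {
  ex <- ann$exons
  sp <- split(seq_len(nrow(ex)), ex$transcript_id)
  keys <- lapply(sp, function(i)
    junction_keys(ex$chrom[i[1L]], ex$strand[i[1L]], ex$start[i], ex$end[i]))
  keys
}

#' Associate transcripts with reference genes through shared splice junctions
#'
#' A transcript is associated with a reference gene when it shares at least
#' one exact splice junction (donor/acceptor coordinate pair on the same
#' chromosome and strand) with a reference transcript. Junction equality is
#' exact: single-base shifts are treated as distinct. Single-exon
#' transcripts have no junctions and are unassociated by default; an
#' opt-in fallback associates them by exonic overlap with a reference
#' transcript on the same strand.
#'
#' @param ann a `txome` whose transcripts are being associated
#' @param reference a `txome` of reference transcripts (gene ids are taken
#'   from here)
#' @param ids transcripts of `ann` to associate (default all)
#' @param single_exon_overlap if TRUE, single-exon transcripts fall back to
#'   exonic-overlap association (default FALSE)
#' @return named character vector: reference gene id or NA per transcript.
#'   When several reference genes share junctions with a transcript the
#'   gene sharing the most junctions wins; ties break lexicographically.
#' @export
shares_splice_junction <- function(ann, reference, ids = NULL,
                                   single_exon_overlap = FALSE) {
  stopifnot(inherits(ann, "txome"), inherits(reference, "txome"))
  if (is.null(ids)) ids <- ann$transcripts$transcript_id
  ref_j <- txome_junctions(reference)
  ref_gene <- reference$transcripts$gene_id
  names(ref_gene) <- reference$transcripts$transcript_id
  jmap <- data.frame(
    key = unlist(ref_j, use.names = FALSE),
    gene = rep(ref_gene[names(ref_j)], lengths(ref_j)),
    stringsAsFactors = FALSE)
  jmap <- unique(jmap)
  genes_by_key <- split(jmap$gene, jmap$key)

  qry_j <- txome_junctions(ann)
  out <- setNames(rep(NA_character_, length(ids)), ids)
  for (id in ids) {
    keys <- qry_j[[id]]
    if (length(keys)) {
      hits <- unlist(genes_by_key[intersect(keys, names(genes_by_key))],
                     use.names = FALSE)
      if (length(hits)) {
        tab <- sort(table(hits), decreasing = TRUE)
        best <- names(tab)[tab == tab[1L]]
        out[id] <- sort(best)[1L]
      }
    } else if (single_exon_overlap) {
      t1 <- ann$transcripts[id, ]
      ref <- reference$transcripts
      ov <- ref$chrom == t1$chrom & ref$strand == t1$strand &
        ref$start <= t1$end & ref$end >= t1$start
      if (any(ov)) out[id] <- sort(unique(ref$gene_id[ov]))[1L]
    }
  }
  out
}

#' Summarize an annotation (genes, transcripts, sources)
#'
#' @param ann a `txome`
#' @return list with `n_genes`, `n_transcripts`, `transcript_gene_ratio`
#'   (2 decimals), `by_source` (count and percent per source), and
#'   `isoforms_per_gene` (table of per-gene isoform counts)
#' @export
summarize_annotation <- function(ann) {
  stopifnot(inherits(ann, "txome"))
  tx <- ann$transcripts
  if (!nrow(tx)) stop("empty annotation")
  n_genes <- length(unique(tx$gene_id))
  n_tx <- nrow(tx)
  src <- factor(tx$source, levels = TX_SOURCES)
  cnt <- table(src)
  by_source <- data.frame(
    source = names(cnt),
    n = as.integer(cnt),
    percent = round(100 * as.integer(cnt) / n_tx, 1),
    stringsAsFactors = FALSE)
  ipg <- table(table(tx$gene_id))
  list(n_genes = n_genes, n_transcripts = n_tx,
       transcript_gene_ratio = round(n_tx / n_genes, 2),
       by_source = by_source,
       isoforms_per_gene = ipg)
}

#' Export 3' termini as BED6
#'
#' One interval of width 1 per transcript at its strand-aware 3' terminus.
#' Coordinates convert from the 1-based inclusive annotation to 0-based
#' half-open BED at this boundary.
#' @param ann a `txome`
#' @param path output BED file
#' @export
export_termini_bed <- function(ann, path) {
  tt <- three_prime_termini(ann)
  gr <- GenomicRanges::GRanges(tt$chrom,
                               IRanges::IRanges(tt$terminus, tt$terminus),
                               strand = tt$strand)
  S4Vectors::mcols(gr)$name <- tt$transcript_id
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
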