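#' Equivalence-class count container
#'
#' Reads are represented only through the set of transcripts they are
#' compatible with (an equivalence class) and a per-library count.
#'
#' @param members list of character vectors (transcript ids per class)
#' @param counts numeric matrix, classes x libraries (a vector is taken as
#'   a single library)
#' @param library_ids library names (default from counts columns)
#' @return object of class `ec_set`
#' @export
ec_set <- function(members, counts, library_ids = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1L)
  counts <- as.matrix(counts)
  if (length(members) != nrow(counts))
    stop("members and counts disagree on the number of classes")
  if (any(counts < 0)) stop("negative class counts")
  if (is.null(library_ids)) library_ids <- colnames(counts)
  if (is.null(library_ids)) library_ids <- paste0("lib", seq_len(ncol(counts)))
  colnames(counts) <- library_ids
  members <- lapply(members, function(m) sort(unique(as.character(m))))
  structure(list(members = members, counts = counts,
                 library_ids = library_ids), class = "ec_set")
}

#' @export
print.ec_set <- function(x, ...) {
  cat("ec_set:", length(x$members), "classes,",
      ncol(x$counts), "libraries,", sum(x$counts), "reads\n")
  invisible(x)
}

#' EM abundance estimation over equivalence classes
#'
#' Iterates the classical rate update
#' \deqn{\alpha_t \leftarrow \sum_c n_c \frac{\alpha_t/\ell_t}{\sum_{t' \in c} \alpha_{t'}/\ell_{t'}}}
#' to its fixed point and returns expected read counts per transcript and
#' library. Reads in classes none of whose members are in `transcripts`
#' are dropped (and reported via the `dropped_reads` attribute).
#'
#' @param ec an `ec_set`
#' @param lengths named numeric vector of effective lengths (here:
#'   transcript lengths; no fragment-length correction is applied)
#' @param transcripts transcripts to quantify (default: all named in
#'   `lengths`)
#' @param max_iter iteration cap (default 1000)
#' @param tol convergence threshold on the maximum change in abundance
#'   proportion (default 1e-8)
#' @return matrix transcripts x libraries of expected counts, with
#'   attribute `dropped_reads` (per library)
#' @export
em_quantify <- function(ec, lengths, transcripts = names(lengths),
                        max_iter = 1000L, tol = 1e-8) {
  stopifnot(inherits(ec, "ec_set"))
  if (is.null(names(lengths))) stop("lengths must be named by transcript")
  if (any(lengths <= 0)) stop("effective lengths must be positive")
  transcripts <- as.character(transcripts)
  if (!length(transcripts)) stop("empty transcript set")
  unknown <- setdiff(unlist(ec$members), names(lengths))
  ## members not in the length table are treated as not retained

  members <- lapply(ec$members, intersect, y = transcripts)
  keep <- lengths(members) > 0L
  dropped <- colSums(ec$counts[!keep, , drop = FALSE])
  members <- members[keep]
  counts <- ec$counts[keep, , drop = FALSE]
  n_lib <- ncol(counts)
  out <- matrix(0, length(transcripts), n_lib,
                dimnames = list(transcripts, colnames(counts)))
  if (!length(members)) {
    attr(out, "dropped_reads") <- dropped
    return(out)
  }

  ## flat (class, transcript) membership index
  cls <- rep(seq_along(members), lengths(members))
  txi <- match(unlist(members), transcripts)
  inv_len <- 1 / lengths[transcripts]
  n_tx <- length(transcripts)
  n_cls <- length(members)
  tot <- colSums(counts)
  tot[tot == 0] <- 1  # all-zero library: abundances stay at start value

  alpha <- matrix(1 / n_tx, n_tx, n_lib)
  for (iter in seq_len(max_iter)) {
    w <- alpha * inv_len                       # tx x lib
    wm <- w[txi, , drop = FALSE]               # membership x lib
    denom <- rowsum(wm, cls, reorder = FALSE)  # class x lib
    denom[denom == 0] <- 1
    share <- wm / denom[cls, , drop = FALSE] * counts[cls, , drop = FALSE]
    expected <- rowsum(share, txi, reorder = FALSE)
    new_alpha <- matrix(0, n_tx, n_lib)
    new_alpha[unique(txi), ] <- sweep(expected, 2L, tot, "/")
    if (max(abs(new_alpha - alpha)) < tol) { alpha <- new_alpha; break }
    alpha <- new_alpha
  }
  w <- alpha * inv_len
  wm <- w[txi, , drop = FALSE]
  denom <- rowsum(wm, cls, reorder = FALSE)
  denom[denom == 0] <- 1
  share <- wm / denom[cls, , drop = FALSE] * counts[cls, , drop = FALSE]
  expected <- rowsum(share, txi, reorder = FALSE)
  out[unique(txi), ] <- expected
  attr(out, "dropped_reads") <- dropped
  out
}

#' Re-quantify after removing transcripts
#'
#' Restricts the EM to a retained transcript set so that reads whose
#' original best assignment was removed can flow to surviving transcripts.
#' Classes whose members were all removed are discarded.
#'
#' @param ec an `ec_set`
#' @param retained transcripts to keep (must be a subset of `lengths`)
#' @param lengths named effective lengths
#' @inheritParams em_quantify
#' @return matrix retained-transcripts x libraries
#' @export
requantify_after_removal <- function(ec, retained, lengths,
                                     max_iter = 1000L, tol = 1e-8) {
  retained <- as.character(retained)
  if (!length(retained)) stop("empty retained set")
  bad <- setdiff(retained, names(lengths))
  if (length(bad)) stop("retained transcripts without lengths: ",
                        paste(head(bad, 5L), collapse = ", "))
  em_quantify(ec, lengths, transcripts = retained,
              max_iter = max_iter, tol = tol)
}

#' Transcripts per million
#'
#' \eqn{TPM_t = 10^6 (c_t/\ell_t) / \sum_u (c_u/\ell_u)} per library.
#' @param counts matrix transcripts x libraries (or vector)
#' @param lengths effective lengths, named or in row order
#' @return matrix of TPM values; per-library columns sum to 1e6 (all-zero
#'   libraries yield all-zero columns with a warning)
#' @export
tpm <- function(counts, lengths) {
  if (is.null(dim(counts)))
    counts <- matrix(counts, ncol = 1L,
                     dimnames = list(names(counts), NULL))
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  rate <- counts / lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("all-zero library(ies): ",
            paste(colnames(counts)[zero], collapse = ", "))
    denom[zero] <- 1
  }
  sweep(rate, 2L, denom, "/") * 1e6
}

#' Parameters for the detected-above-background cascade
#'
#' @param min_read_pairs library inclusion threshold on raw read pairs
#'   (default 1e7: libraries below 10 million read pairs are dropped)
#' @param allowed_chrom_pattern regex for chromosomes retained (default:
#'   autosomes and sex chromosomes; contigs fail the match)
#' @param max_zero_fraction a transcript is dropped when its estimated
#'   count is zero in at least `ceiling(N * max_zero_fraction)` of the N
#'   designated quantitation libraries (default 1/3)
#' @param min_length minimum spliced length retained (default 201:
#'   transcripts of 200 nucleotides or fewer are dropped)
#' @param zero_tol estimated counts at or below this value count as zero
#'   (the EM stops at a finite tolerance, so starved transcripts can park
#'   a vanishing fraction of a read just above zero)
#' @export
dabg_params <- function(min_read_pairs = 1e7,
                        allowed_chrom_pattern = "^(chr)?([0-9]+|X|Y)$",
                        max_zero_fraction = 1 / 3,
                        min_length = 201,
                        zero_tol = 1e-3) {
  stopifnot(max_zero_fraction > 0, max_zero_fraction <= 1,
            min_length >= 0, min_read_pairs >= 0)
  list(min_read_pairs = min_read_pairs,
       allowed_chrom_pattern = allowed_chrom_pattern,
       max_zero_fraction = max_zero_fraction,
       min_length = min_length,
       zero_tol = zero_tol)
}

ledger_row <- function(ann, ids, step, note = "") {
  tx <- ann$transcripts[ids, , drop = FALSE]
  src <- factor(tx$source, levels = TX_SOURCES)
  cnt <- table(src)
  data.frame(step = step,
             n_genes = length(unique(tx$gene_id)),
             n_transcripts = nrow(tx),
             n_ensembl = as.integer(cnt["ensembl"]),
             n_stringtie = as.integer(cnt["stringtie"]),
             n_aptardi = as.integer(cnt["aptardi"]),
             note = note,
             stringsAsFactors = FALSE)
}

check_ledger <- function(ledger) {
  stopifnot(all(diff(ledger$n_transcripts) <= 0))
  srcsum <- ledger$n_ensembl + ledger$n_stringtie + ledger$n_aptardi
  stopifnot(all(srcsum == ledger$n_transcripts))
  ledger
}

zero_fail <- function(counts, quant_libs, params) {
  n <- length(quant_libs)
  need <- ceiling(n * params$max_zero_fraction)
  zeros <- rowSums(counts[, quant_libs, drop = FALSE] <= params$zero_tol)
  zeros >= need
}

#' Detected-above-background transcriptome generation and quantitation
#'
#' The ordered cascade: (1) drop libraries with too few raw read pairs;
#' (2) drop transcripts not on autosomal/sex chromosomes; (3) quantify by
#' EM in the designated quantitation libraries; (4) drop transcripts with
#' zero estimated counts in at least a third of those libraries, and
#' transcripts at or below the minimum length, simultaneously; (5)
#' re-quantify all retained libraries against the survivors so that reads
#' from removed transcripts can be reassigned; (6) re-apply the zero-count
#' rule. A filter ledger records genes, transcripts and per-source counts
#' at every step.
#'
#' @param ann a `txome`
#' @param ec an `ec_set` covering all libraries
#' @param meta data.frame with columns `library_id`, `strain`, `batch`,
#'   `raw_read_pairs`, and logical `loading_control`; the zero-count rule
#'   is evaluated on the non-control ("quantitation") libraries only
#' @param params a `dabg_params()` list
#' @return list with `annotation` (surviving `txome`), `counts` (final
#'   re-quantified matrix over all retained libraries), `ledger`
#'   (data.frame), `meta` (retained libraries), `quant_libraries`
#' @export
build_dabg <- function(ann, ec, meta, params = dabg_params()) {
  stopifnot(inherits(ann, "txome"), inherits(ec, "ec_set"))
  need <- c("library_id", "strain", "batch", "raw_read_pairs",
            "loading_control")
  if (!all(need %in% names(meta)))
    stop("meta lacks columns: ", paste(setdiff(need, names(meta)),
                                       collapse = ", "))
  if (!all(ec$library_ids %in% meta$library_id))
    stop("libraries in ec without metadata")

  ## step 1: library depth filter
  keep_lib <- meta$library_id[meta$raw_read_pairs >= params$min_read_pairs]
  if (!length(keep_lib)) stop("all libraries removed by the depth filter")
  meta_kept <- meta[meta$library_id %in% keep_lib, , drop = FALSE]
  quant_libs <- meta_kept$library_id[!meta_kept$loading_control]
  if (!length(quant_libs)) stop("no quantitation libraries remain")
  ec <- ec_set(ec$members,
               ec$counts[, intersect(ec$library_ids, keep_lib), drop = FALSE])

  ids0 <- ann$transcripts$transcript_id
  ledger <- ledger_row(ann, ids0, "input",
                       sprintf("%d libraries retained of %d",
                               length(keep_lib), nrow(meta)))

  ## step 2: chromosome filter
  ids1 <- ids0[grepl(params$allowed_chrom_pattern,
                     ann$transcripts$chrom)]
  ledger <- rbind(ledger, ledger_row(ann, ids1, "chromosome_filter",
                                     params$allowed_chrom_pattern))

  ## step 3: quantitation of the current set
  lens <- setNames(ann$transcripts$length, ann$transcripts$transcript_id)
  counts1 <- em_quantify(ec, lens, transcripts = ids1)

  ## step 4: zero-count rule and length rule, simultaneously
  fail_zero <- zero_fail(counts1, quant_libs, params)
  fail_len <- ann$transcripts[ids1, "length"] < params$min_length
  ids2 <- ids1[!(fail_zero | fail_len)]
  ledger <- rbind(ledger, ledger_row(
    ann, ids2, "zero_count_and_length_filter",
    sprintf("zero in >= %d of %d libraries; length <= %d",
            ceiling(length(quant_libs) * params$max_zero_fraction),
            length(quant_libs), params$min_length - 1L)))
  if (!length(ids2)) stop("no transcripts survive the first filter round")

  ## step 5: re-quantitation against survivors (all retained libraries)
  counts2 <- requantify_after_removal(ec, ids2, lens)

  ## step 6: re-apply the zero-count rule
  fail_zero2 <- zero_fail(counts2, quant_libs, params)
  ids3 <- ids2[!fail_zero2]
  ledger <- rbind(ledger, ledger_row(ann, ids3, "requantified_zero_filter"))
  check_ledger(ledger)

  list(annotation = subset_txome(ann, ids3),
       counts = counts2[ids3, , drop = FALSE],
       ledger = ledger,
       meta = meta_kept,
       quant_libraries = quant_libs,
       params = params)
}
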