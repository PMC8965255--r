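#' Upper-quartile depth normalization
#'
#' Each library is rescaled so that its 75th percentile of counts —
#' computed over transcripts with a nonzero count in at least one library —
#' equals the across-library mean of those percentiles. Using the mean of
#' per-library upper quartiles (rather than a fixed reference library)
#' makes scale factors change smoothly when libraries are added.
#'
#' @param counts matrix transcripts x libraries of estimated counts
#' @return rescaled matrix with attribute `scale_factors`
#' @export
upper_quartile_normalize <- function(counts) {
  counts <- as.matrix(counts)
  expressed <- rowSums(counts) > 0
  if (!any(expressed)) stop("no transcript has a nonzero count")
  uq <- apply(counts[expressed, , drop = FALSE], 2L, quantile, probs = 0.75)
  if (any(uq == 0)) {
    bad <- colnames(counts)[uq == 0]
    stop("degenerate library (upper quartile is 0): ",
         paste(bad, collapse = ", "))
  }
  ref <- mean(uq)
  sf <- ref / uq
  out <- sweep(counts, 2L, sf, "*")
  attr(out, "scale_factors") <- sf
  out
}

#' Moderated log transform
#'
#' A variance-stabilizing transform for downstream statistics that depend
#' only on a monotone log-type scale: `y = log2(count + c)` followed by
#' per-transcript shrinkage of each library's value toward the transcript
#' mean with weight `lambda / (lambda + n_libraries)`. At `lambda = 0` the
#' transform is a plain shifted log2; as `lambda` grows all libraries
#' collapse to the transcript mean.
#'
#' @param counts depth-normalized count matrix (transcripts x libraries)
#' @param pseudocount shift `c` (default 1)
#' @param lambda shrinkage weight parameter (default 1)
#' @return matrix of transformed values with a `transform` provenance
#'   attribute
#' @export
regularized_log <- function(counts, pseudocount = 1, lambda = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (lambda < 0) stop("lambda must be non-negative")
  y <- log2(counts + pseudocount)
  n <- ncol(y)
  w <- lambda / (lambda + n)
  m <- rowMeans(y)
  out <- w * m + (1 - w) * y
  attr(out, "transform") <-
    sprintf("log2(count + %g) with mean shrinkage lambda=%g (moderated log, not the GLM-based reference rlog)",
            pseudocount, lambda)
  out
}

#' Empirical-Bayes batch adjustment
#'
#' Parametric location/scale batch adjustment (ComBat, via the sva
#' package): per-transcript batch locations are shrunk toward a
#' batch-level normal prior and scales toward an inverse-gamma prior, then
#' removed. A single batch is an identity operation; a batch structure
#' confounded 1:1 with strain triggers a warning because the batch effect
#' is then not identifiable. Transcripts with zero variance are passed
#' through unchanged.
#'
#' @param expr matrix transcripts x libraries on a transform (log) scale
#' @param batches batch label per library
#' @param strains optional strain label per library, used only for the
#'   confounding check
#' @return adjusted matrix
#' @export
batch_adjust <- function(expr, batches, strains = NULL) {
  expr <- as.matrix(expr)
  batches <- as.character(batches)
  if (length(batches) != ncol(expr))
    stop("one batch label per library required")
  if (length(unique(batches)) < 2L) return(expr)
  tab <- table(batches)
  if (any(tab < 2L))
    stop("every batch needs at least 2 libraries: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  if (!is.null(strains)) {
    per_batch <- tapply(as.character(strains), batches,
                        function(s) length(unique(s)))
    if (all(per_batch == 1L))
      warning("batches are confounded 1:1 with strain; batch effect is not identifiable")
  }
  v <- apply(expr, 1L, var)
  constant <- v == 0 | is.na(v)
  out <- expr
  if (any(!constant)) {
    adj <- suppressMessages(
      sva::ComBat(dat = expr[!constant, , drop = FALSE], batch = batches))
    out[!constant, ] <- adj
  }
  out
}

#' Strain-mean expression summarization
#'
#' Arithmetic mean of each strain's libraries. Loading-control libraries
#' (metadata flag `loading_control`) are excluded: they exist to monitor
#' technical reproducibility and are not part of the RI-panel statistics.
#'
#' @param expr matrix transcripts x libraries
#' @param meta data.frame with `library_id`, `strain`, and logical
#'   `loading_control`
#' @return matrix transcripts x strains
#' @export
strain_means <- function(expr, meta) {
  expr <- as.matrix(expr)
  m <- meta[match(colnames(expr), meta$library_id), , drop = FALSE]
  if (anyNA(m$library_id)) stop("libraries without metadata")
  keep <- !m$loading_control
  if (!any(keep)) stop("no RI-panel libraries present")
  expr <- expr[, keep, drop = FALSE]
  strain <- as.character(m$strain[keep])
  g <- factor(strain, levels = sort(unique(strain)))
  out <- t(rowsum(t(expr), g) / as.vector(table(g)))
  out
}
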