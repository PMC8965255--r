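#' LOD score of single-marker regression
#'
#' \eqn{LOD = (n/2) \log_{10}(RSS_0 / RSS_1)} comparing the intercept-only
#' model with the single-marker regression; computed from group sums. A
#' perfect fit (RSS1 = 0) returns the cap. Equivalent to
#' \eqn{-(n/2)\log_{10}(1 - r^2)}.
#'
#' @param y trait values (one per strain)
#' @param g biallelic genotype coded 0/1 (same order as `y`)
#' @param cap LOD ceiling for perfect fits (default 50)
#' @return LOD score; NA for a monomorphic marker
#' @export
lod_score <- function(y, g, cap = 50) {
  ok <- complete.cases(y, g)
  y <- y[ok]; g <- g[ok]
  n <- length(y)
  if (n < 3L) stop("need >= 3 strains")
  if (length(unique(g)) < 2L) return(NA_real_)
  rss0 <- sum((y - mean(y))^2)
  if (rss0 == 0) return(0)
  m1 <- mean(y[g == min(g)]); m2 <- mean(y[g == max(g)])
  rss1 <- sum((y[g == min(g)] - m1)^2) + sum((y[g == max(g)] - m2)^2)
  if (rss1 == 0) return(cap)
  min((n / 2) * log10(rss0 / rss1), cap)
}

## Vectorized LOD over permutation copies (columns of Y) and markers
## (columns of G, coded 0/1). Same arithmetic as lod_score, via group sums.
lod_matrix <- function(Y, G, cap = 50) {
  Y <- as.matrix(Y); G <- as.matrix(G)
  n <- nrow(Y)
  stopifnot(nrow(G) == n)
  n1 <- colSums(G)
  n0 <- n - n1
  poly <- n1 > 0 & n0 > 0
  tot <- colSums(Y)
  syy <- colSums(Y^2) - tot^2 / n          # RSS0 per trait column
  s1 <- crossprod(Y, G)                    # traits x markers: sum y over g=1
  ssb <- sweep(s1^2, 2L, pmax(n1, 1L), "/") +
    sweep(sweep(s1, 1L, tot, FUN = function(a, b) b - a)^2, 2L,
          pmax(n0, 1L), "/") - outer(tot^2 / n, rep(1, ncol(G)))
  rss1 <- pmax(sweep(-ssb, 1L, syy, "+"), 0)
  lod <- (n / 2) * log10(sweep(1 / rss1, 1L, syy, "*"))
  lod[!is.finite(lod)] <- cap
  lod <- pmin(lod, cap)
  zero <- syy == 0
  if (any(zero)) lod[zero, ] <- 0
  lod[, !poly] <- NA_real_
  lod
}

#' Genome scan by marker regression
#'
#' LOD at every marker (after SDP collapsing, every marker is an SDP
#' representative). Trait and genotype strains are intersected; markers
#' monomorphic on the intersection get NA and are skipped downstream.
#'
#' @param trait named numeric vector (strain means)
#' @param geno a `genotype_matrix` (see [simulate_ri_genotypes()] /
#'   [collapse_to_sdp()])
#' @param cap LOD ceiling
#' @return object of class `qtl_scan`: data.frame marker, chrom, pos, lod
#'   with attributes `strains` (those used) and `trait`
#' @export
genome_scan <- function(trait, geno, cap = 50) {
  stopifnot(inherits(geno, "genotype_matrix"))
  strains <- intersect(names(trait), geno$strain_ids)
  if (length(strains) < 3L) stop("fewer than 3 overlapping strains")
  y <- trait[strains]
  G <- geno$alleles[strains, , drop = FALSE]
  lod <- drop(lod_matrix(matrix(y, ncol = 1L), G, cap = cap))
  out <- data.frame(marker = geno$markers$id,
                    chrom = geno$markers$chrom,
                    pos = geno$markers$pos,
                    lod = as.numeric(lod),
                    stringsAsFactors = FALSE)
  structure(out, class = c("qtl_scan", "data.frame"),
            strains = strains)
}

#' Peak of a genome scan
#'
#' Single global maximum; ties break by first chromosome then position.
#' @param scan a `qtl_scan`
#' @return one-row data.frame: marker, chrom, pos, lod
#' @export
scan_peak <- function(scan) {
  ok <- !is.na(scan$lod)
  s <- scan[ok, , drop = FALSE]
  s <- s[order(-s$lod, match(s$chrom, unique(scan$chrom)), s$pos), ]
  s[1L, , drop = FALSE]
}

#' Permutation genome-wide thresholds
#'
#' Strain labels of the trait are permuted jointly across all markers
#' (preserving the marker correlation structure); the genome-wide maximum
#' LOD per permutation forms the null. Thresholds are empirical (1-alpha)
#' quantiles of the maxima.
#'
#' @param trait named strain means
#' @param geno `genotype_matrix`
#' @param n_perm number of permutations (>= 100; default 1000)
#' @param alphas genome-wide levels (default 0.01, 0.05, 0.63)
#' @param seed optional RNG seed for reproducibility
#' @param cap LOD ceiling
#' @return object of class `threshold_set`: list with `maxima`,
#'   `thresholds` (named by alpha), `n_perm`
#' @export
permutation_thresholds <- function(trait, geno, n_perm = 1000L,
                                   alphas = c(0.01, 0.05, 0.63),
                                   seed = NULL, cap = 50) {
  stopifnot(n_perm >= 100L)
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  strains <- intersect(names(trait), geno$strain_ids)
  y <- trait[strains]
  G <- geno$alleles[strains, , drop = FALSE]
  n <- length(y)
  P <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
  lod <- lod_matrix(P, G, cap = cap)
  maxima <- apply(lod, 1L, max, na.rm = TRUE)
  thresholds <- quantile(maxima, probs = 1 - alphas, names = FALSE)
  names(thresholds) <- as.character(alphas)
  structure(list(maxima = maxima, thresholds = thresholds,
                 n_perm = n_perm), class = "threshold_set")
}

#' Empirical genome-wide p-value
#'
#' \eqn{p = (1 + \#\{max_{perm} \ge observed\}) / (n_{perm} + 1)}.
#' @param observed observed genome-wide maximum LOD
#' @param thresholds a `threshold_set` (its permutation maxima are used)
#' @export
empirical_p <- function(observed, thresholds) {
  maxima <- if (inherits(thresholds, "threshold_set"))
    thresholds$maxima else thresholds
  (1 + sum(maxima >= observed)) / (length(maxima) + 1)
}

#' Bayesian credible interval for a QTL
#'
#' The posterior over marker positions on one chromosome is proportional
#' to 10^LOD. Markers are ranked by LOD and accumulated until their
#' normalized mass reaches the coverage; the interval spans the
#' accumulated markers' positions, expanded by one flanking marker on
#' each side where one exists.
#'
#' @param scan a `qtl_scan`
#' @param chromosome chromosome to summarize
#' @param coverage posterior mass (default 0.95)
#' @param expand expand to flanking markers (default TRUE)
#' @return list: `lo`, `hi` (positions), `markers` (accumulated ids)
#' @export
bayes_credible_interval <- function(scan, chromosome, coverage = 0.95,
                                    expand = TRUE) {
  s <- scan[scan$chrom == chromosome & !is.na(scan$lod), , drop = FALSE]
  if (!nrow(s)) stop("no markers on chromosome ", chromosome)
  s <- s[order(s$pos), , drop = FALSE]
  ## scale before exponentiating to keep 10^LOD finite
  mass <- 10^(s$lod - max(s$lod))
  mass <- mass / sum(mass)
  ord <- order(-mass)
  acc <- ord[seq_len(which(cumsum(mass[ord]) >= coverage)[1L])]
  lo_i <- min(acc); hi_i <- max(acc)
  if (expand) {
    lo_i <- max(1L, lo_i - 1L)
    hi_i <- min(nrow(s), hi_i + 1L)
  }
  list(lo = s$pos[lo_i], hi = s$pos[hi_i], markers = s$marker[acc])
}

#' Per-chromosome QTL peaks with tiers and credible intervals
#'
#' For each chromosome whose maximum LOD reaches the suggestive
#' threshold, reports the peak with its empirical genome-wide p-value,
#' tier label, and 95% Bayesian credible interval.
#'
#' @param scan a `qtl_scan`
#' @param thresholds a `threshold_set` with alphas including the tier
#'   levels
#' @param tiers named vector of alpha levels defining tiers (default
#'   significant = 0.05, suggestive = 0.63)
#' @param coverage credible-interval coverage
#' @return data.frame of peaks (possibly empty): chrom, marker, pos, lod,
#'   p, tier, ci_lo, ci_hi
#' @export
qtl_peaks <- function(scan, thresholds,
                      tiers = c(significant = 0.05, suggestive = 0.63),
                      coverage = 0.95) {
  tiers <- sort(tiers)   # strictest first
  out <- list()
  for (ch in unique(scan$chrom)) {
    s <- scan[scan$chrom == ch & !is.na(scan$lod), , drop = FALSE]
    if (!nrow(s)) next
    i <- order(-s$lod, s$pos)[1L]
    p <- empirical_p(s$lod[i], thresholds)
    tier <- names(tiers)[p < tiers]
    if (!length(tier)) next
    ci <- bayes_credible_interval(scan, ch, coverage = coverage)
    out[[ch]] <- data.frame(chrom = ch, marker = s$marker[i],
                            pos = s$pos[i], lod = s$lod[i], p = p,
                            tier = tier[1L], ci_lo = ci$lo, ci_hi = ci$hi,
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), marker = character(),
                      pos = numeric(), lod = numeric(), p = numeric(),
                      tier = character(), ci_lo = numeric(),
                      ci_hi = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Covariate-conditioned genome scan
#'
#' \eqn{LOD = (n/2)\log_{10}(RSS_{cov}/RSS_{cov+marker})}, both models
#' containing the covariate marker's allele term. Markers collinear with
#' the covariate (identical or complementary allele vector on the
#' intersected strains) get LOD 0.
#'
#' @param trait named strain means
#' @param geno `genotype_matrix`
#' @param covariate_marker marker id to condition on
#' @param cap LOD ceiling
#' @return a `qtl_scan`
#' @export
covariate_scan <- function(trait, geno, covariate_marker, cap = 50) {
  stopifnot(inherits(geno, "genotype_matrix"))
  strains <- intersect(names(trait), geno$strain_ids)
  if (length(strains) < 4L) stop("fewer than 4 overlapping strains")
  y <- trait[strains]
  G <- geno$alleles[strains, , drop = FALSE]
  j <- match(covariate_marker, geno$markers$id)
  if (is.na(j)) stop("unknown covariate marker ", covariate_marker)
  cv <- G[, j]
  if (length(unique(cv)) < 2L) stop("covariate marker is monomorphic")
  n <- length(y)
  fit0 <- stats::lm(y ~ cv)
  rss0 <- sum(stats::resid(fit0)^2)
  lod <- vapply(seq_len(ncol(G)), function(m) {
    g <- G[, m]
    if (length(unique(g)) < 2L) return(NA_real_)
    if (all(g == cv) || all(g == 1 - cv)) return(0)
    rss1 <- sum(stats::resid(stats::lm(y ~ cv + g))^2)
    if (rss1 == 0) return(cap)
    min((n / 2) * log10(rss0 / rss1), cap)
  }, numeric(1))
  out <- data.frame(marker = geno$markers$id, chrom = geno$markers$chrom,
                    pos = geno$markers$pos, lod = lod,
                    stringsAsFactors = FALSE)
  structure(out, class = c("qtl_scan", "data.frame"), strains = strains)
}

#' Classify a QTL peak as local or distal to a transcript
#'
#' Local iff the peak lies on the transcript's chromosome within `window`
#' bases (inclusive) of the transcript midpoint; distal otherwise. The
#' window is an explicit convention, not a biological constant.
#'
#' @param peak_chrom,peak_pos peak location
#' @param tx_chrom,tx_start,tx_end transcript span
#' @param window distance threshold in bases (default 1e7)
#' @return "local" or "distal"
#' @export
classify_eqtl <- function(peak_chrom, peak_pos, tx_chrom, tx_start, tx_end,
                          window = 1e7) {
  mid <- (tx_start + tx_end) / 2
  ifelse(peak_chrom == tx_chrom & abs(peak_pos - mid) <= window,
         "local", "distal")
}
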