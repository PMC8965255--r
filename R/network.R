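#' Coexpression network parameters
#'
#' @param beta soft-threshold power applied to |Pearson correlation|
#'   (default 7, chosen in this pipeline's tier of analyses to approximate
#'   scale-free topology on strain-mean expression)
#' @param min_module_size smallest accepted module (default 5)
#' @param split_sensitivity integer 0..5 controlling how aggressively
#'   dendrogram branches are split; larger is more aggressive (default 4)
#' @param merge_height cohesion ceiling on the 1-TOM scale: a branch whose
#'   internal merge height exceeds this is never accepted as a module
#'   (default 0.99)
#' @export
network_params <- function(beta = 7, min_module_size = 5,
                           split_sensitivity = 4, merge_height = 0.99) {
  stopifnot(beta >= 1, min_module_size >= 2,
            split_sensitivity >= 0, split_sensitivity <= 5,
            merge_height > 0, merge_height <= 1)
  list(beta = beta, min_module_size = min_module_size,
       split_sensitivity = split_sensitivity, merge_height = merge_height)
}

#' Unsigned soft-thresholded adjacency
#'
#' \eqn{a_{ij} = |cor(x_i, x_j)|^\beta} with unit diagonal; correlations
#' are Pearson across strains (columns of `expr`).
#'
#' @param expr matrix transcripts x strains (typically strain means)
#' @param params a [network_params()] list
#' @return symmetric matrix in [0,1]
#' @export
adjacency <- function(expr, params = network_params()) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need >= 3 strains")
  v <- apply(expr, 1L, var)
  if (any(v == 0))
    stop("constant expression row(s): ",
         paste(head(rownames(expr)[v == 0], 5L), collapse = ", "))
  a <- abs(cor(t(expr)))^params$beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit index
#'
#' Whole-network connectivities \eqn{k_i = \sum_{j \ne i} a_{ij}} are
#' binned on a log10 scale; the fit is the R^2 of the regression of
#' log10 p(k) on log10 mean-k over occupied bins. Used as a diagnostic
#' for the soft-threshold power.
#'
#' @param adj adjacency matrix (ignored when `k` is given)
#' @param k optional precomputed connectivity vector
#' @param n_bins number of log-spaced bins (default 10)
#' @return R^2 in [0,1], or NA (flagged by attribute `undefined`) when
#'   fewer than 2 bins are occupied
#' @export
scale_free_fit <- function(adj = NULL, k = NULL, n_bins = 10) {
  if (is.null(k)) {
    stopifnot(!is.null(adj))
    if (nrow(adj) < 20L) stop("need >= 20 nodes")
    k <- rowSums(adj) - diag(adj)
  }
  k <- k[k > 0]
  if (!length(k)) return(structure(NA_real_, undefined = TRUE))
  lk <- log10(k)
  brks <- seq(min(lk), max(lk), length.out = n_bins + 1L)
  brks[1L] <- brks[1L] - 1e-9
  bin <- cut(lk, brks, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  occupied <- cnt > 0
  if (sum(occupied) < 2L) return(structure(NA_real_, undefined = TRUE))
  p <- cnt[occupied] / length(k)
  mean_k <- tapply(k, bin, mean)[occupied]
  fit <- stats::lm(log10(p) ~ log10(as.numeric(mean_k)))
  suppressWarnings(summary(fit)$r.squared)   # perfect fits warn harmlessly
}

#' Topological overlap similarity
#'
#' \eqn{TOM_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})}
#' with \eqn{\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}}; diagonal 1.
#'
#' @param adj symmetric adjacency in [0,1] with unit diagonal
#' @return TOM similarity matrix in [0,1]
#' @export
tom_similarity <- function(adj) {
  adj <- as.matrix(adj)
  stopifnot(isSymmetric(unname(adj)), all(abs(diag(adj) - 1) < 1e-12))
  l <- adj %*% adj - 2 * adj        # removes the u = i and u = j terms
  k <- rowSums(adj) - 1
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

## Recursive branch cut on an average-linkage dendrogram of 1 - TOM.
## At each internal node: if the branch is incohesive (merge height above
## the ceiling) it must be split further; otherwise it is split only when
## both children reach the minimum size and the height gap to the taller
## child exceeds a threshold scaled by split_sensitivity.
cut_tree_recursive <- function(hc, params) {
  n <- length(hc$order)
  heights <- hc$height
  rng <- max(heights) - min(heights)
  gap_thr <- (1 - params$split_sensitivity / 5) * rng

  members_of <- function(node) {
    if (node < 0) return(-node)
    unlist(lapply(hc$merge[node, ], members_of))
  }
  height_of <- function(node) if (node < 0) 0 else heights[node]

  groups <- list()
  descend <- function(node) {
    if (node < 0) { groups[[length(groups) + 1L]] <<- -node; return(invisible()) }
    h <- heights[node]
    kids <- hc$merge[node, ]
    sizes <- vapply(kids, function(x) length(members_of(x)), numeric(1))
    child_h <- vapply(kids, height_of, numeric(1))
    if (h > params$merge_height) {
      descend(kids[1L]); descend(kids[2L]); return(invisible())
    }
    gap <- h - max(child_h)
    if (all(sizes >= params$min_module_size) && gap >= gap_thr) {
      descend(kids[1L]); descend(kids[2L])
    } else {
      groups[[length(groups) + 1L]] <<- members_of(node)
    }
    invisible()
  }
  descend(nrow(hc$merge))
  groups
}

#' Detect coexpression modules by recursive branch cutting
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity,
#' followed by a documented simplified recursive branch cut (see
#' [network_params()] for the knobs). Accepted branches of at least
#' `min_module_size` leaves become modules, labeled `M1`, `M2`, ... in
#' decreasing size order (ties broken by first member id); all other
#' leaves form the unassigned pool.
#'
#' @param diss dissimilarity matrix (1 - TOM), square and symmetric
#' @param params a [network_params()] list
#' @return list: `modules` (named list of member id vectors), `labels`
#'   (named vector, `"unassigned"` for the pool), `unassigned`
#' @export
detect_modules <- function(diss, params = network_params()) {
  diss <- as.matrix(diss)
  ids <- rownames(diss)
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(diss)))
  n <- nrow(diss)
  labels <- setNames(rep("unassigned", n), ids)
  if (n < params$min_module_size)
    return(list(modules = list(), labels = labels, unassigned = ids))
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  groups <- cut_tree_recursive(hc, params)
  groups <- Filter(function(g) length(g) >= params$min_module_size, groups)
  ## additional cohesion guard at acceptance: branch top height must be
  ## below the ceiling (branches forced down by incohesion already are)
  mods <- lapply(groups, function(g) sort(ids[g]))
  if (length(mods)) {
    ord <- order(-lengths(mods), vapply(mods, `[`, character(1), 1L))
    mods <- mods[ord]
    names(mods) <- paste0("M", seq_along(mods))
    for (nm in names(mods)) labels[mods[[nm]]] <- nm
  }
  list(modules = mods, labels = labels,
       unassigned = ids[labels == "unassigned"])
}

#' Module eigengene
#'
#' First principal component of the strains x members matrix after
#' per-transcript standardization. The sign is fixed so that the mean
#' correlation with member profiles is positive; variance explained is
#' the leading eigenvalue over the trace.
#'
#' @param expr matrix transcripts x strains
#' @param members transcript ids in the module (>= 2)
#' @return list: `eigengene` (named per-strain scores, unit norm),
#'   `variance_explained`, `module_size`
#' @export
module_eigengene <- function(expr, members) {
  if (length(members) < 2L) stop("module size must be >= 2")
  x <- as.matrix(expr)[members, , drop = FALSE]
  sds <- apply(x, 1L, sd)
  if (all(sds == 0)) stop("rank-0 module: all members constant")
  x <- x[sds > 0, , drop = FALSE]
  xs <- t(scale(t(x)))                       # standardize per transcript
  m <- t(xs)                                 # strains x members
  sv <- svd(m)
  score <- sv$u[, 1L]
  if (mean(cor(score, m)) < 0) score <- -score
  names(score) <- colnames(expr)
  list(eigengene = score,
       variance_explained = sv$d[1L]^2 / sum(sv$d^2),
       module_size = length(members))
}

#' Intra-modular connectivity
#'
#' \eqn{k_i = \sum_{j \in module, j \ne i} a_{ij}}; the hub is the member
#' with maximal k (ties break lexicographically).
#'
#' @param adj adjacency matrix
#' @param members module member ids
#' @return list: `k_within` (named vector), `hub`
#' @export
intramodular_connectivity <- function(adj, members) {
  a <- adj[members, members, drop = FALSE]
  k <- rowSums(a) - diag(a)
  names(k) <- members
  hub <- sort(names(k)[k == max(k)])[1L]
  list(k_within = k, hub = hub)
}
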