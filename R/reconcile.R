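#' Pairwise path-length distance matrix of a tree
#'
#' D_T(t, t') = pl(t, t'), the sum of branch lengths on the path between the
#' two leaves.
#'
#' @param tree A \code{"phylo"} tree with branch lengths.
#' @return A symmetric numeric matrix with zero diagonal, labeled by leaf.
#' @export
tree_distance_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  D <- ape::cophenetic.phylo(tree)
  D[sort(rownames(D)), sort(rownames(D))]
}

#' Distance matrix from a nucleotide alignment
#'
#' Reference distances for branch-length reconciliation, computed from a
#' multiple alignment as Jukes-Cantor corrected distances (default) or raw
#' p-distances.
#'
#' @param alignment Character matrix (rows = taxa) or \code{DNAbin}.
#' @param model \code{"JC69"} or \code{"raw"}.
#' @return Symmetric numeric distance matrix.
#' @export
alignment_distance_matrix <- function(alignment, model = c("JC69", "raw")) {
  model <- match.arg(model)
  if (!inherits(alignment, "DNAbin"))
    alignment <- ape::as.DNAbin(alignment)
  as.matrix(ape::dist.dna(alignment, model = model, pairwise.deletion = TRUE))
}

# usable pairwise ratios D / D_T over pairs present in both matrices with
# D_T > 0 (excluded pairs counted via attribute "n_excluded")
ratio_set <- function(D, D_T) {
  taxa <- intersect(rownames(D), rownames(D_T))
  if (length(taxa) < 2L) stop("no common taxon pairs between D and D_T")
  D <- D[taxa, taxa]; D_T <- D_T[taxa, taxa]
  ut <- upper.tri(D)
  d <- D[ut]; dt <- D_T[ut]
  usable <- !is.na(d) & !is.na(dt) & dt > 0
  if (!any(usable)) stop("no usable taxon pairs (all D_T zero or missing)")
  structure(list(d = d[usable], dt = dt[usable]),
            n_excluded = sum(!usable))
}

#' Robust multiplicative constant by the alpha-trimmed mean of ratios
#'
#' Builds the multiset C of pairwise ratios D(t,t')/D_T(t,t') over taxon
#' pairs present in both matrices with D_T > 0, sorts it, drops
#' \code{floor(alpha * |C|)} elements from each end, and returns the mean of
#' the remainder. With \code{alpha = 0} this is the plain mean; the default
#' \code{alpha = 1/3} tolerates up to a third of the ratios being corrupted
#' on either side.
#'
#' @param D Reference distance matrix (taxa in rownames).
#' @param D_T Distance matrix of the tree to be rescaled.
#' @param alpha Trimming fraction in \[0, 0.5).
#' @return The estimated constant c.
#' @export
trimmed_mean_constant <- function(D, D_T, alpha = 1 / 3) {
  if (alpha < 0 || alpha >= 0.5) stop("'alpha' must be in [0, 0.5)")
  rs <- ratio_set(D, D_T)
  ratios <- sort(rs$d / rs$dt)
  m <- length(ratios)
  k <- floor(alpha * m)
  mean(ratios[(k + 1L):(m - k)])
}

#' Least-squares multiplicative constant
#'
#' Minimizes the sum of squared differences sum (D - c * D_T)^2 over usable
#' pairs; the closed-form minimizer is sum(D * D_T) / sum(D_T^2).
#'
#' @inheritParams trimmed_mean_constant
#' @return The estimated constant c.
#' @export
least_squares_constant <- function(D, D_T) {
  rs <- ratio_set(D, D_T)
  sum(rs$d * rs$dt) / sum(rs$dt^2)
}

#' Minimax multiplicative constant
#'
#' Minimizes the maximum absolute difference max |D - c * D_T| over usable
#' pairs. The objective is piecewise-linear and convex in c; the minimum is
#' attained either at a single-pair ratio or where an increasing and a
#' decreasing residual line cross, so the exact optimum is found by
#' enumerating the candidate crossings c = (D_i + D_j) / (D_T_i + D_T_j).
#'
#' @inheritParams trimmed_mean_constant
#' @return The estimated constant c.
#' @export
minimax_constant <- function(D, D_T) {
  rs <- ratio_set(D, D_T)
  d <- rs$d; dt <- rs$dt
  obj <- function(c) max(abs(d - c * dt))
  if (length(d) > 1500L) {
    # very large pair sets: golden-section on the convex objective
    hi <- max(d / dt)
    o <- stats::optimize(obj, c(0, hi + 1), tol = 1e-12)
    return(o$minimum)
  }
  cand <- c(d / dt, as.vector(outer(d, d, "+") / outer(dt, dt, "+")))
  cand <- unique(cand[is.finite(cand) & cand >= 0])
  vals <- vapply(cand, obj, numeric(1))
  cand[which.min(vals)]
}

#' Rescale all branch lengths of a tree
#'
#' @param tree A \code{"phylo"} tree with branch lengths.
#' @param c Positive multiplicative constant.
#' @return The tree with every branch length multiplied by \code{c}.
#' @export
apply_constant <- function(tree, c) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!is.numeric(c) || length(c) != 1L || c <= 0) stop("'c' must be > 0")
  tree$edge.length <- tree$edge.length * c
  tree
}

#' Reconcile branch lengths of input trees against a reference matrix
#'
#' Estimates one multiplicative constant per tree (comparing the tree's
#' path-length distances to the reference distances over its own taxa) and
#' rescales the tree. Skip reconciliation entirely when all input branch
#' lengths were estimated under the same model of sequence evolution.
#'
#' @param trees List of \code{"phylo"} trees with branch lengths.
#' @param D Reference distance matrix covering the trees' taxa.
#' @param method \code{"trimmed"} (default), \code{"lsq"}, or
#'   \code{"minimax"}.
#' @param alpha Trimming fraction for \code{method = "trimmed"}.
#' @return List of rescaled trees, with the per-tree constants attached as
#'   attribute \code{"constants"}.
#' @export
reconcile_trees <- function(trees, D, method = c("trimmed", "lsq", "minimax"),
                            alpha = 1 / 3) {
  method <- match.arg(method)
  if (inherits(trees, "phylo")) trees <- list(trees)
  cs <- vapply(trees, function(tr) {
    D_T <- tree_distance_matrix(tr)
    switch(method,
           trimmed = trimmed_mean_constant(D, D_T, alpha),
           lsq = least_squares_constant(D, D_T),
           minimax = minimax_constant(D, D_T))
  }, numeric(1))
  out <- mapply(apply_constant, trees, cs, SIMPLIFY = FALSE)
  attr(out, "constants") <- cs
  out
}
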