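#' Restrict a tree to a subset of its leaves
#'
#' Computes the restriction T|X: the minimal subtree connecting the leaves in
#' \code{labels}, rooted at their last common ancestor, with all degree-two
#' vertices suppressed. Branch lengths along suppressed chains are summed, so
#' path lengths between retained leaves are preserved.
#'
#' @param tree A \code{"phylo"} object.
#' @param labels Leaf labels to keep (nonempty subset of \code{leaf_labels(tree)}).
#' @return The restricted \code{"phylo"} tree.
#' @examples
#' tr <- parse_newick("((a:1,b:1):2,c:1);")
#' write_newick(restrict_tree(tr, c("a", "c")))  # (a:3,c:1);
#' @export
restrict_tree <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  labels <- as.character(labels)
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing) > 0L)
    stop("labels not in tree: ", paste(missing, collapse = ", "))
  if (length(labels) == 0L) stop("'labels' must be nonempty")
  if (length(labels) == 1L) {
    # a single-leaf tree; carry the root-to-leaf path length as pendant length
    tr <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = labels,
               Nnode = 1L)
    class(tr) <- "phylo"
    if (!is.null(tree$edge.length)) tr$edge.length <- 0
    return(tr)
  }
  if (setequal(labels, tree$tip.label)) return(tree)
  res <- ape::keep.tip(tree, labels)
  res$root.edge <- NULL
  res
}

# Per-tree lookup tables used throughout: tip index by label, mrca node
# matrix, node depth in edges from the root, and node distance from the root
# in branch-length units (NULL when lengths are absent).
tree_tables <- function(tree) {
  n <- length(tree$tip.label)
  mr <- if (n >= 2L) ape::mrca(tree) else matrix(1L, 1L, 1L,
    dimnames = list(tree$tip.label, tree$tip.label))
  unit <- tree
  unit$edge.length <- rep(1, nrow(tree$edge))
  depth <- ape::node.depth.edgelength(unit)
  rootdist <- if (!is.null(tree$edge.length))
    ape::node.depth.edgelength(tree) else NULL
  list(labels = tree$tip.label, mrca = mr, depth = depth,
       rootdist = rootdist, root = n + 1L, n = n)
}

#' Last common ancestor of a set of leaves
#'
#' Returns the internal ape node index of the deepest vertex whose clade
#' contains every label in \code{labels} (the leaf's own index for a
#' singleton set).
#'
#' @param tree A \code{"phylo"} object.
#' @param labels Nonempty subset of the tree's leaf labels.
#' @return Integer node index (tips are \code{1..n}, root is \code{n+1}).
#' @export
tree_lca <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  labels <- as.character(labels)
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing) > 0L)
    stop("labels not in tree: ", paste(missing, collapse = ", "))
  if (length(labels) == 0L) stop("'labels' must be nonempty")
  idx <- match(labels, tree$tip.label)
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, labels)
}

#' Path length between two leaves
#'
#' Sum of branch lengths along the unique path between leaves \code{x} and
#' \code{y}: pl(x, y) = pl(x, lca) + pl(y, lca).
#'
#' @param tree A \code{"phylo"} object with branch lengths.
#' @param x,y Leaf labels.
#' @return Nonnegative numeric; zero iff \code{x == y}.
#' @export
path_length <- function(tree, x, y) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  miss <- setdiff(c(x, y), tree$tip.label)
  if (length(miss) > 0L)
    stop("labels not in tree: ", paste(miss, collapse = ", "))
  if (identical(x, y)) return(0)
  rd <- ape::node.depth.edgelength(tree)
  a <- tree_lca(tree, c(x, y))
  ix <- match(x, tree$tip.label); iy <- match(y, tree$tip.label)
  (rd[ix] - rd[a]) + (rd[iy] - rd[a])
}

#' Nontrivial clades of a rooted tree
#'
#' Returns the clades (descendant leaf-label sets of internal vertices) of
#' the tree. With \code{nontrivial = TRUE} (default) the full leaf set and
#' singletons are excluded, matching the clade sets used by the
#' Robinson-Foulds and resolution measures.
#'
#' @param tree A \code{"phylo"} object.
#' @param nontrivial Drop the root clade (all leaves)?
#' @return A list of character vectors (sorted labels), each a clade.
#' @export
tree_clades <- function(tree, nontrivial = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 2L) return(list())
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- lapply(pp, function(ix) sort(labs[ix]))
  if (nontrivial) out <- out[vapply(out, length, 1L) < n]
  out
}

clade_keys <- function(tree) {
  vapply(tree_clades(tree), paste, character(1), collapse = "\r")
}

#' Resolved rooted triplets of a tree
#'
#' Enumerates every resolved triplet xy|z of the tree (the pair x,y whose
#' last common ancestor is strictly below the last common ancestor of all
#' three). Triples spanned by a polytomy are unresolved and omitted. A
#' binary tree on n leaves has choose(n, 3) resolved triplets.
#'
#' @param tree A \code{"phylo"} object.
#' @return Character vector of canonical triplet keys \code{"x,y|z"} with the
#'   cherry pair sorted; empty for trees with fewer than 3 leaves or stars.
#' @export
tree_triplets <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 3L) return(character(0))
  tb <- tree_tables(tree)
  cmb <- utils::combn(n, 3L)
  i <- cmb[1L, ]; j <- cmb[2L, ]; k <- cmb[3L, ]
  dij <- tb$depth[tb$mrca[cbind(i, j)]]
  dik <- tb$depth[tb$mrca[cbind(i, k)]]
  djk <- tb$depth[tb$mrca[cbind(j, k)]]
  labs <- tb$labels
  key <- function(a, b, c) {
    ab <- cbind(labs[a], labs[b])
    ab <- cbind(pmin(ab[, 1], ab[, 2]), pmax(ab[, 1], ab[, 2]))
    paste0(ab[, 1], ",", ab[, 2], "|", labs[c])
  }
  s1 <- dij > dik & dij > djk   # ij|k
  s2 <- dik > dij & dik > djk   # ik|j
  s3 <- djk > dij & djk > dik   # jk|i
  res <- c(if (any(s1)) key(i[s1], j[s1], k[s1]),
           if (any(s2)) key(i[s2], k[s2], j[s2]),
           if (any(s3)) key(j[s3], k[s3], i[s3]))
  if (is.null(res)) character(0) else res
}

#' Does one tree display another?
#'
#' \code{t_big} displays \code{t_small} when the restriction of \code{t_big}
#' to the leaves of \code{t_small} is a refinement of \code{t_small}, i.e.
#' every clade of \code{t_small} is a clade of the restriction. Informally:
#' all ancestral relationships of \code{t_small} are preserved, up to
#' polytomies.
#'
#' @param t_big A \code{"phylo"} tree whose leaf set contains that of
#'   \code{t_small}.
#' @param t_small A \code{"phylo"} tree.
#' @return Logical.
#' @export
displays <- function(t_big, t_small) {
  stopifnot(inherits(t_big, "phylo"), inherits(t_small, "phylo"))
  if (!all(t_small$tip.label %in% t_big$tip.label))
    stop("leaves of 't_small' are not a subset of leaves of 't_big'")
  r <- restrict_tree(t_big, t_small$tip.label)
  all(clade_keys(t_small) %in% clade_keys(r))
}
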