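# Shared machinery for the graph-guided supertree recursions.
#
# For each input tree we precompute its mrca matrix and node depths once
# (tree_tables); a recursion level over taxon set U then obtains the edge
# bookkeeping without materializing restricted trees: in T|Ui the last common
# ancestor of a pair equals the root of the restriction iff its depth in T
# equals the minimal pairwise-lca depth over Ui.

precompute_treeinfo <- function(trees) {
  lapply(trees, function(tr) {
    stopifnot(inherits(tr, "phylo"))
    tree_tables(tr)
  })
}

# Edge bookkeeping over taxon set U (character vector, sorted).
# Returns a list of matrices (|U| x |U|, upper use both halves):
#   w          number of restricted trees supporting the pair (lca below root)
#   cooccur    number of restricted trees containing both
#   contradict cooccur - w
graph_counts <- function(infos, U) {
  nu <- length(U)
  W <- matrix(0L, nu, nu, dimnames = list(U, U))
  CO <- matrix(0L, nu, nu, dimnames = list(U, U))
  for (tb in infos) {
    pos <- match(tb$labels, U)
    keep <- which(!is.na(pos))
    if (length(keep) < 2L) next
    ui <- keep                      # tip indices in this tree
    up <- pos[keep]                 # positions in U
    M <- tb$mrca[ui, ui, drop = FALSE]
    d <- matrix(tb$depth[M], nrow = length(ui))
    diag(d) <- NA
    rootdepth <- min(d, na.rm = TRUE)
    supp <- (d > rootdepth)
    diag(supp) <- FALSE
    CO[up, up] <- CO[up, up] + 1L
    W[up, up] <- W[up, up] + supp
  }
  diag(CO) <- 0L
  list(w = W, cooccur = CO, contradict = CO - W)
}

#' Build graph of a tree collection over a taxon set
#'
#' Constructs the weighted graph used by the Build/MinCut/Modified-MinCut
#' recursions: vertices are the taxa in \code{U}; an edge \{x,y\} is present
#' whenever some input tree, restricted to its taxa within \code{U}, places
#' the last common ancestor of x and y strictly below its root (equivalently,
#' contributes a triplet xy|z with z in \code{U}). Edge weight \code{w} is
#' the number of supporting restricted trees; \code{n_cooccur} counts
#' restricted trees containing both taxa and \code{n_contradict = n_cooccur
#' - w} counts those placing the pair's ancestor at their root.
#'
#' @param trees List of \code{"phylo"} input trees.
#' @param U Character vector of taxa; defaults to the union of all leaf sets.
#' @return An object of class \code{"taxon_graph"}: a data frame with columns
#'   \code{x}, \code{y}, \code{w}, \code{n_cooccur}, \code{n_contradict}
#'   (one row per stored edge, \code{w >= 1}), with attribute
#'   \code{vertices}.
#' @examples
#' trees <- lapply(c("((a,b),c);", "((b,c),d);"), parse_newick)
#' taxon_graph(trees)
#' @export
taxon_graph <- function(trees, U = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  infos <- precompute_treeinfo(trees)
  allU <- sort(unique(unlist(lapply(infos, `[[`, "labels"))))
  if (is.null(U)) U <- allU
  U <- sort(as.character(U))
  missing <- setdiff(U, allU)
  if (length(missing) > 0L)
    stop("taxa not present in any input tree: ",
         paste(missing, collapse = ", "))
  cnt <- graph_counts(infos, U)
  idx <- which(upper.tri(cnt$w) & cnt$w >= 1L, arr.ind = TRUE)
  g <- data.frame(
    x = U[idx[, 1]], y = U[idx[, 2]],
    w = cnt$w[idx], n_cooccur = cnt$cooccur[idx],
    n_contradict = cnt$contradict[idx],
    stringsAsFactors = FALSE)
  attr(g, "vertices") <- U
  class(g) <- c("taxon_graph", class(g))
  g
}

# Union-find components of vertices 1..n under an edge list (two integer
# vectors). Returns an integer component id per vertex.
uf_components <- function(n, from, to) {
  parent <- seq_len(n)
  for (k in seq_along(from)) {
    a <- from[k]
    while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
    b <- to[k]
    while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- integer(n)
  for (i in seq_len(n)) {
    a <- i
    while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
    roots[i] <- a
  }
  match(roots, sort(unique(roots)))
}

quote_newick_label <- function(x) {
  bad <- grepl("[\\s,:;()\\[\\]']", x, perl = TRUE)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

# Assemble a newick fragment from child fragments, ordered by their
# lexicographically smallest leaf (stored as attribute "minlab").
combine_children <- function(children) {
  ord <- order(vapply(children, attr, character(1), "minlab"))
  frag <- paste0("(", paste(vapply(children[ord], as.character, character(1)),
                            collapse = ","), ")")
  attr(frag, "minlab") <- attr(children[ord[[1]]][[1]], "minlab")
  frag
}

leaf_fragment <- function(label) {
  frag <- quote_newick_label(label)
  attr(frag, "minlab") <- label
  frag
}

finish_newick <- function(frag) {
  parse_newick(paste0(as.character(frag), ";"))
}
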