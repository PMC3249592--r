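#' Normalized Robinson-Foulds distance between rooted trees
#'
#' Counts the nontrivial clades (leaf sets of size at least 2, excluding the
#' full leaf set) present in exactly one of the two trees, normalized by the
#' total number of nontrivial clades of both trees, giving a value in
#' \[0, 1\]. Two star trees have distance 0 by convention.
#'
#' @param t1,t2 Rooted \code{"phylo"} trees on the same leaf set.
#' @return Numeric in \[0, 1\].
#' @examples
#' a <- parse_newick("((a,b),(c,d));"); b <- parse_newick("(((a,b),c),d);")
#' rf_distance(a, b)  # 0.5
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must have identical leaf sets (restrict first)")
  c1 <- clade_keys(t1); c2 <- clade_keys(t2)
  denom <- length(c1) + length(c2)
  if (denom == 0L) return(0)
  (length(setdiff(c1, c2)) + length(setdiff(c2, c1))) / denom
}

#' Rooted triplet comparison of a model tree and a supertree
#'
#' Classifies every 3-subset of the common leaf set into exactly one of five
#' bins: resolved identically in both trees (\code{same}), resolved
#' differently (\code{diff}), resolved only in the model tree (\code{r1}),
#' resolved only in the second tree (\code{r2}), or unresolved in both
#' (\code{x}). The triplet distance is
#' d_TR = (diff + r1 + r2) / (same + diff + r1 + r2), with 0/0 taken as 0.
#'
#' @param t1 The model (reference) tree.
#' @param t2 The tree compared against it; same leaf set.
#' @return An object of class \code{"triplet_comparison"}: list with the five
#'   counts, \code{n} (leaves), and \code{d_tr}.
#' @examples
#' m <- parse_newick("((a,b),(c,d));"); s <- parse_newick("((a,b),c,d);")
#' triplet_comparison(m, s)  # same 2, r1 2, d_tr 0.5
#' @export
triplet_comparison <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must have identical leaf sets (restrict first)")
  n <- length(t1$tip.label)
  if (n < 3L) {
    out <- list(same = 0L, diff = 0L, r1 = 0L, r2 = 0L, x = 0L,
                n = n, d_tr = 0)
    class(out) <- "triplet_comparison"
    return(out)
  }
  code1 <- triple_codes(t1)
  code2 <- triple_codes(t2, order_from = t1)
  res1 <- code1 > 0L; res2 <- code2 > 0L
  same <- sum(res1 & res2 & code1 == code2)
  diffn <- sum(res1 & res2 & code1 != code2)
  r1 <- sum(res1 & !res2)
  r2 <- sum(!res1 & res2)
  xx <- sum(!res1 & !res2)
  denom <- same + diffn + r1 + r2
  out <- list(same = same, diff = diffn, r1 = r1, r2 = r2, x = xx, n = n,
              d_tr = if (denom == 0L) 0 else (diffn + r1 + r2) / denom)
  class(out) <- "triplet_comparison"
  out
}

#' @export
print.triplet_comparison <- function(x, ...) {
  cat("triplet comparison over", x$n, "leaves:\n")
  cat(sprintf("  same %d  diff %d  r1 %d  r2 %d  x %d\n",
              x$same, x$diff, x$r1, x$r2, x$x))
  cat(sprintf("  triplet distance d_TR = %.4f\n", x$d_tr))
  invisible(x)
}

# Per-3-subset topology code in a fixed leaf order: 0 = unresolved,
# 1/2/3 = the cherry excludes the third/second/first leaf of the subset.
triple_codes <- function(tree, order_from = NULL) {
  labs <- if (is.null(order_from)) sort(tree$tip.label) else
    sort(order_from$tip.label)
  n <- length(labs)
  tb <- tree_tables(tree)
  perm <- match(labs, tb$labels)
  D <- matrix(tb$depth[tb$mrca], tb$n, tb$n)[perm, perm]
  cmb <- utils::combn(n, 3L)
  i <- cmb[1L, ]; j <- cmb[2L, ]; k <- cmb[3L, ]
  dij <- D[cbind(i, j)]; dik <- D[cbind(i, k)]; djk <- D[cbind(j, k)]
  code <- integer(ncol(cmb))
  code[dij > dik & dij > djk] <- 1L
  code[dik > dij & dik > djk] <- 2L
  code[djk > dij & djk > dik] <- 3L
  code
}

#' Resolution of a rooted tree
#'
#' Number of nontrivial clades divided by n - 2, the count attained by a
#' fully resolved rooted binary tree on n leaves (the root clade and leaves
#' are not counted). 0 for a star, 1 for a binary tree.
#'
#' @param tree A \code{"phylo"} tree with at least 3 leaves.
#' @return Numeric in \[0, 1\].
#' @export
tree_resolution <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 3L) stop("resolution requires at least 3 leaves")
  length(tree_clades(tree)) / (n - 2)
}

#' Maximum agreement subtree (MAST) score of two rooted trees
#'
#' Size of the largest leaf subset X such that the restrictions of both
#' trees to X are identical (up to child order), computed by dynamic
#' programming over node pairs with exact maximum-weight bipartite matching
#' at polytomies. The normalized score divides by the leaf count of
#' \code{t1} (the model tree), so pruning taxa from \code{t2} lowers it.
#'
#' @param t1 The model tree (normalization reference).
#' @param t2 A rooted tree; leaf sets need not be equal.
#' @return List with \code{size} (integer) and \code{normalized}
#'   (\code{size / |L(t1)|}).
#' @examples
#' mast_score(parse_newick("((a,b),c);"), parse_newick("((a,c),b);"))$size  # 2
#' @export
mast_score <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  common <- intersect(t1$tip.label, t2$tip.label)
  n1 <- length(t1$tip.label)
  if (length(common) == 0L)
    return(list(size = 0L, normalized = 0))
  if (length(common) == 1L)
    return(list(size = 1L, normalized = 1 / n1))
  a <- restrict_tree(t1, common)
  b <- restrict_tree(t2, common)
  size <- mast_dp(a, b)
  list(size = as.integer(size), normalized = size / n1)
}

mast_dp <- function(a, b) {
  na <- length(a$tip.label); nb <- length(b$tip.label)
  Na <- na + a$Nnode; Nb <- nb + b$Nnode
  cha <- children_list(a); chb <- children_list(b)
  # descendant-leaf label sets per node
  seta <- node_leafsets(a); setb <- node_leafsets(b)
  M <- matrix(0, Na, Nb)
  orda <- postorder_nodes(a); ordb <- postorder_nodes(b)
  for (u in orda) {
    for (v in ordb) {
      if (u <= na && v <= nb) {
        M[u, v] <- as.numeric(a$tip.label[u] == b$tip.label[v])
      } else if (u <= na) {
        M[u, v] <- as.numeric(a$tip.label[u] %in% setb[[v]])
      } else if (v <= nb) {
        M[u, v] <- as.numeric(b$tip.label[v] %in% seta[[u]])
      } else {
        best <- 0
        for (cu in cha[[u]]) best <- max(best, M[cu, v])
        for (cv in chb[[v]]) best <- max(best, M[u, cv])
        w <- M[cha[[u]], chb[[v]], drop = FALSE]
        best <- max(best, max_matching(w))
        M[u, v] <- best
      }
    }
  }
  M[na + 1L, nb + 1L]
}

children_list <- function(tree) {
  N <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", N)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; c <- tree$edge[k, 2]
    ch[[p]] <- c(ch[[p]], c)
  }
  ch
}

node_leafsets <- function(tree) {
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  out <- vector("list", N)
  for (i in seq_len(n)) out[[i]] <- tree$tip.label[i]
  ch <- children_list(tree)
  for (u in postorder_nodes(tree)) {
    if (u > n) out[[u]] <- unlist(out[ch[[u]]], use.names = FALSE)
  }
  out
}

postorder_nodes <- function(tree) {
  # children before parents: order internal nodes by decreasing subtree rank
  n <- length(tree$tip.label)
  re <- ape::reorder.phylo(tree, "postorder")
  c(seq_len(n), unique(re$edge[, 1]))
}

# Exact maximum-weight bipartite matching of a small nonnegative matrix.
# Rows are matched injectively into columns (rows <= cols after transpose).
max_matching <- function(w) {
  if (length(w) == 0L) return(0)
  if (nrow(w) > ncol(w)) w <- t(w)
  p <- nrow(w); q <- ncol(w)
  if (p == 1L) return(max(w))
  if (p <= 12L) {
    # DP across columns over bitmask of matched rows
    nstates <- bitwShiftL(1L, p)
    best <- rep(0, nstates)
    for (cc in seq_len(q)) {
      nxt <- best
      for (s in 0:(nstates - 1L)) {
        base <- best[s + 1L]
        for (r in seq_len(p)) {
          bit <- bitwShiftL(1L, r - 1L)
          if (bitwAnd(s, bit) == 0L) {
            cand <- base + w[r, cc]
            if (cand > nxt[bitwOr(s, bit) + 1L])
              nxt[bitwOr(s, bit) + 1L] <- cand
          }
        }
      }
      best <- nxt
    }
    return(max(best))
  }
  # large two-sided polytomies: maximum-weight matching via igraph
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, p), rep(TRUE, q)),
    edges = as.vector(rbind(rep(seq_len(p), each = q),
                            p + rep(seq_len(q), times = p))))
  res <- igraph::max_bipartite_match(g, weights = as.vector(t(w)) + 1e-9)
  mt <- res$matching[seq_len(p)]
  sum(w[cbind(seq_len(p), as.integer(mt) - p)], na.rm = TRUE)
}

#' Compare a (possibly nonplenary) supertree to its model tree
#'
#' Restricts the model tree to the supertree's taxa, then computes the
#' normalized Robinson-Foulds distance, the triplet comparison, and the
#' resolution on the common leaf set. The MAST score is normalized by the
#' leaf count of the unrestricted model tree, so excluding taxa lowers it.
#'
#' @param model The model tree; its leaf set must contain the supertree's.
#' @param tree The supertree to evaluate.
#' @param mast Compute the MAST score (the most expensive metric)?
#' @return An object of class \code{"tree_comparison"}: list with
#'   \code{resolution}, \code{rf_norm}, \code{triplet}
#'   (a [triplet_comparison()]), \code{d_tr}, \code{mast},
#'   \code{mast_norm}, and \code{n_excluded_taxa}.
#' @export
compare_trees <- function(model, tree, mast = TRUE) {
  stopifnot(inherits(model, "phylo"), inherits(tree, "phylo"))
  if (!all(tree$tip.label %in% model$tip.label))
    stop("supertree contains taxa absent from the model tree")
  excl <- length(model$tip.label) - length(tree$tip.label)
  m <- restrict_tree(model, tree$tip.label)
  n <- length(tree$tip.label)
  trip <- triplet_comparison(m, tree)
  out <- list(
    resolution = if (n >= 3L) tree_resolution(tree) else 0,
    rf_norm = rf_distance(m, tree),
    triplet = trip,
    d_tr = trip$d_tr,
    mast = NA_integer_, mast_norm = NA_real_,
    n_excluded_taxa = excl)
  if (mast) {
    ms <- mast_score(model, tree)
    out$mast <- ms$size
    out$mast_norm <- ms$normalized
  }
  class(out) <- "tree_comparison"
  out
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat("tree comparison (supertree vs model)\n")
  cat(sprintf("  resolution  %.4f\n", x$resolution))
  cat(sprintf("  RF (norm)   %.4f\n", x$rf_norm))
  cat(sprintf("  d_TR        %.4f\n", x$d_tr))
  if (!is.na(x$mast))
    cat(sprintf("  MAST        %d (normalized %.4f)\n", x$mast, x$mast_norm))
  if (x$n_excluded_taxa > 0)
    cat(sprintf("  excluded taxa: %d\n", x$n_excluded_taxa))
  invisible(x)
}
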