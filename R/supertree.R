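#' Build supertree of compatible rooted trees
#'
#' The classical all-or-nothing recursion: at each level the connected
#' components of the Build graph over the current taxon set become the
#' children of the supertree node. If at any level with three or more taxa
#' the graph is connected, the collection is incompatible and a distinguished
#' incompatibility marker is returned instead of a tree.
#'
#' @param trees Nonempty list of rooted \code{"phylo"} trees, each with at
#'   least two leaves.
#' @return A \code{"phylo"} supertree on the union of all leaf sets that
#'   displays every input tree, or an object of class
#'   \code{"polysup_incompatible"} (test with [is_incompatible()]).
#' @examples
#' trees <- lapply(c("((a,b),c);", "((b,c),d);"), parse_newick)
#' write_newick(build_supertree(trees))  # (((a,b),c),d);
#' @export
build_supertree <- function(trees) {
  st_run(trees, method = "build")
}

#' MinCut (MC) supertree
#'
#' Extends Build to conflicting inputs: whenever the Build graph over the
#' current taxon set is connected, edges supported by every restricted input
#' tree containing the pair (\code{n_contradict == 0}) are contracted, the
#' union of all global minimum cuts of the contracted weighted graph is
#' removed, and the recursion continues on the resulting components. The
#' output is always a plenary tree on the union of leaf sets; on compatible
#' inputs it displays every input tree.
#'
#' @inheritParams build_supertree
#' @return A \code{"phylo"} supertree.
#' @export
mincut_supertree <- function(trees) {
  st_run(trees, method = "mc")
}

#' Modified MinCut (MMC) supertree
#'
#' As [mincut_supertree()], but only contradicted edges
#' (\code{n_contradict >= 1}) are candidates for deletion at the cut step;
#' uncontradicted edges are protected by an effectively infinite cut weight
#' (unanimously supported pairs are contracted as in MC). Every input-tree
#' clade whose pairs no other input tree contradicts appears as a clade of
#' the output.
#'
#' @inheritParams build_supertree
#' @return A \code{"phylo"} supertree.
#' @export
modified_mincut_supertree <- function(trees) {
  st_run(trees, method = "mmc")
}

#' Test for the incompatibility marker returned by Build
#'
#' @param x Any object.
#' @return Logical: is \code{x} the distinguished incompatibility result?
#' @export
is_incompatible <- function(x) inherits(x, "polysup_incompatible")

st_run <- function(trees, method) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("'trees' must be a nonempty list of trees")
  if (any(!vapply(trees, inherits, TRUE, "phylo")))
    stop("'trees' must be a list of \"phylo\" objects")
  if (any(vapply(trees, function(t) length(t$tip.label), 1L) < 2L))
    stop("every input tree must have at least two leaves")
  infos <- precompute_treeinfo(trees)
  U <- sort(unique(unlist(lapply(infos, `[[`, "labels"))))
  frag <- st_recurse(infos, U, method)
  if (is.null(frag)) {
    return(structure(
      list(message = "input trees are incompatible (Build graph connected)"),
      class = "polysup_incompatible"))
  }
  finish_newick(frag)
}

# Recursion over taxon set U (sorted character). Returns a newick fragment
# with attribute "minlab", or NULL to signal incompatibility (build only).
st_recurse <- function(infos, U, method) {
  nu <- length(U)
  if (nu == 1L) return(leaf_fragment(U))
  if (nu == 2L) return(combine_children(lapply(U, leaf_fragment)))
  cnt <- graph_counts(infos, U)
  idx <- which(upper.tri(cnt$w) & cnt$w >= 1L, arr.ind = TRUE)
  from <- idx[, 1]; to <- idx[, 2]
  comp <- uf_components(nu, from, to)
  if (max(comp) == 1L) {
    if (method == "build") return(NULL)
    parts <- st_cut(cnt, from, to, nu, protect_uncontradicted = (method == "mmc"))
    if (is.null(parts)) {
      # contraction collapse: all taxa merged into one supervertex
      warning("contraction merged a conflicted component into one vertex; ",
              "emitting a polytomy over ", nu, " taxa")
      return(combine_children(lapply(U, leaf_fragment)))
    }
    comp <- parts
  }
  children <- lapply(split(U, comp), function(sub) {
    st_recurse(infos, sub, method)
  })
  if (any(vapply(children, is.null, TRUE))) return(NULL)
  combine_children(children)
}

# The MC/MMC disconnection step on a connected graph. Returns component ids
# over the vertices after deleting every edge lying in at least one global
# minimum cut of the contracted graph, or NULL on contraction collapse.
st_cut <- function(cnt, from, to, nu, protect_uncontradicted = FALSE) {
  w <- cnt$w[cbind(from, to)]
  contradict <- cnt$contradict[cbind(from, to)]
  unct <- contradict == 0L
  super <- uf_components(nu, from[unct], to[unct])
  k <- max(super)
  if (k == 1L) return(NULL)
  sf <- super[from]; st <- super[to]
  between <- sf != st
  # aggregate parallel edges between supervertices
  a <- pmin(sf[between], st[between]); b <- pmax(sf[between], st[between])
  key <- paste(a, b)
  wt <- w[between]
  if (protect_uncontradicted) wt[unct[between]] <- Inf  # vacuous by construction
  agg <- rowsum(wt, key)
  pair <- do.call(rbind, lapply(strsplit(rownames(agg), " "), as.integer))
  big <- sum(agg[is.finite(agg)]) + 1
  cap <- ifelse(is.finite(agg[, 1]), agg[, 1], big)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  g <- igraph::add_edges(g, t(pair))
  cutval <- igraph::min_cut(g, capacity = cap, value.only = TRUE)
  in_min_cut <- vapply(seq_len(nrow(pair)), function(e) {
    igraph::max_flow(g, source = pair[e, 1], target = pair[e, 2],
                     capacity = cap)$value <= cutval + 1e-9
  }, TRUE)
  # delete original edges mapping onto min-cut-crossing contracted edges
  del_keys <- rownames(agg)[in_min_cut]
  orig_key <- paste(pmin(sf, st), pmax(sf, st))
  keep <- !(between & orig_key %in% del_keys)
  uf_components(nu, from[keep], to[keep])
}
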