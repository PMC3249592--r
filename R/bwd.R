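#' Leaf-pair distance table for Build-with-Distances
#'
#' For every ordered leaf pair (x, y), lambda(x, y) is the branch-length
#' distance from x up to the last common ancestor of x and y, averaged over
#' the input trees containing both. lambda is not symmetric; the co-occurrence
#' count is. The table is computed once from the full input trees and reused
#' at every recursion level of [bwd_supertree()].
#'
#' @param trees Nonempty list of rooted \code{"phylo"} trees, all with branch
#'   lengths.
#' @return An object of class \code{"lambda_table"}: list with \code{labels},
#'   \code{lambda} (ordered-pair matrix, \code{NA} where the pair never
#'   co-occurs), \code{cooccur} (symmetric integer matrix), and
#'   \code{membership} (labels x trees logical matrix).
#' @examples
#' lt <- lambda_table(list(parse_newick("((a:1,b:2):1,c:4);")))
#' lt$lambda["a", "b"]  # 1
#' lt$lambda["b", "a"]  # 2
#' @export
lambda_table <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("'trees' must be nonempty")
  for (i in seq_along(trees)) {
    if (is.null(trees[[i]]$edge.length))
      stop("input tree ", i, " has no branch lengths")
  }
  infos <- precompute_treeinfo(trees)
  labels <- sort(unique(unlist(lapply(infos, `[[`, "labels"))))
  n <- length(labels)
  lsum <- matrix(0, n, n, dimnames = list(labels, labels))
  co <- matrix(0L, n, n, dimnames = list(labels, labels))
  membership <- matrix(FALSE, n, length(trees),
                       dimnames = list(labels, NULL))
  for (ti in seq_along(infos)) {
    tb <- infos[[ti]]
    pos <- match(tb$labels, labels)
    membership[pos, ti] <- TRUE
    if (tb$n < 2L) next
    rd <- tb$rootdist[seq_len(tb$n)]
    lcad <- matrix(tb$rootdist[tb$mrca], tb$n, tb$n)
    lam <- rd - lcad            # row x: distance from x down from lca(x, y)
    lsum[pos, pos] <- lsum[pos, pos] + lam
    co[pos, pos] <- co[pos, pos] + 1L
  }
  diag(co) <- 0L
  lambda <- ifelse(co > 0L, lsum / pmax(co, 1L), NA_real_)
  structure(list(labels = labels, lambda = lambda, cooccur = co,
                 membership = membership),
            class = "lambda_table")
}

#' Primary evidence that x pairs with y rather than z
#'
#' p(x, y, z) = max\{0, lambda(x, z) - lambda(x, y)\}; defined as 0 when
#' \{x, y\} or \{x, z\} never occur together in an input tree.
#'
#' @param lt A [lambda_table()].
#' @param x,y,z Distinct leaf labels.
#' @return Nonnegative numeric.
#' @export
primary_evidence <- function(lt, x, y, z) {
  stopifnot(inherits(lt, "lambda_table"))
  if (anyDuplicated(c(x, y, z)) > 0L)
    stop("x, y, z must be distinct labels")
  labs <- lt$labels
  miss <- setdiff(c(x, y, z), labs)
  if (length(miss) > 0L) stop("labels not in table: ", paste(miss, collapse = ", "))
  if (lt$cooccur[x, y] == 0L || lt$cooccur[x, z] == 0L) return(0)
  max(0, lt$lambda[x, z] - lt$lambda[x, y])
}

#' Accumulated confirmed support (SAC) of a leaf pair
#'
#' SAC(x, y, U) = sum over z in U \ \{x, y\} of
#' min\{p(x, y, z), p(y, x, z)\}. Symmetric in (x, y) and nonnegative.
#'
#' @param lt A [lambda_table()].
#' @param x,y Distinct labels, both in \code{U}.
#' @param U Character vector, the current clade of the recursion.
#' @return Nonnegative numeric.
#' @export
support_sac <- function(lt, x, y, U) {
  sac_pair(lt, x, y, U, use_max = FALSE)
}

#' Accumulated support with maximum aggregation (SACmax)
#'
#' SACmax(x, y, U) = sum over z in U \ \{x, y\} of
#' max\{p(x, y, z), p(y, x, z)\}. Always at least [support_sac()].
#'
#' @inheritParams support_sac
#' @return Nonnegative numeric.
#' @export
support_sac_max <- function(lt, x, y, U) {
  sac_pair(lt, x, y, U, use_max = TRUE)
}

sac_pair <- function(lt, x, y, U, use_max) {
  stopifnot(inherits(lt, "lambda_table"))
  U <- as.character(U)
  if (!x %in% U || !y %in% U) stop("x and y must be elements of U")
  if (identical(x, y)) stop("x and y must be distinct")
  zs <- setdiff(U, c(x, y))
  if (length(zs) == 0L) return(0)
  pxy <- p_vec(lt, x, y, zs)
  pyx <- p_vec(lt, y, x, zs)
  sum(if (use_max) pmax(pxy, pyx) else pmin(pxy, pyx))
}

# vector of p(a, b, z) over z
p_vec <- function(lt, a, b, zs) {
  if (lt$cooccur[a, b] == 0L) return(rep(0, length(zs)))
  laz <- lt$lambda[a, zs]
  ok <- lt$cooccur[a, zs] >= 1L
  p <- pmax(0, laz - lt$lambda[a, b])
  p[!ok | is.na(p)] <- 0
  p
}

# Cross-tree distance-edge witnesses, computed once over all taxa.
# crossz[[x]] is an n x n logical matrix Wx with Wx[y, z] = TRUE when
#   cooccur(x, y) >= 1, cooccur(x, z) >= 1, no input tree contains all of
#   {x, y, z}, and lambda(x, y) < lambda(x, z),
# i.e. z witnesses the distance edge {x, y} from x's side.
cross_witnesses <- function(lt) {
  n <- length(lt$labels)
  k <- ncol(lt$membership)
  out <- vector("list", n)
  for (x in seq_len(n)) {
    cx <- lt$cooccur[x, ] >= 1L
    if (!any(cx)) { out[[x]] <- matrix(FALSE, n, n); next }
    # trees containing both x and each other taxon
    Cx <- lt$membership & matrix(lt$membership[x, ], n, k, byrow = TRUE)
    shared3 <- (Cx %*% t(Cx)) > 0      # [y, z]: some tree holds x, y and z
    lx <- lt$lambda[x, ]
    lesser <- outer(lx, lx, "<")       # [y, z]: lambda(x,y) < lambda(x,z)
    lesser[is.na(lesser)] <- FALSE
    W <- lesser & !shared3
    W <- W & cx & matrix(cx, n, n, byrow = TRUE)
    W[x, ] <- FALSE; W[, x] <- FALSE
    out[[x]] <- W
  }
  out
}

#' BWD graph over a taxon set
#'
#' The Build-with-Distances graph extends the Build graph over \code{U} with
#' distance edges: \{x, y\} is added when the pair co-occurs in some input
#' tree and there is a witness z in \code{U} such that x and z also co-occur,
#' no single input tree contains all three leaves, and
#' lambda(x, y) < lambda(x, z) (strictly).
#'
#' @param trees List of \code{"phylo"} input trees with branch lengths.
#' @param lt Optional precomputed [lambda_table()] for \code{trees}.
#' @param U Taxon subset; defaults to all taxa.
#' @return A data frame with columns \code{x}, \code{y}, \code{provenance}
#'   (\code{"build"} or \code{"distance"}); attribute \code{vertices}.
#' @export
bwd_graph <- function(trees, lt = NULL, U = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(lt)) lt <- lambda_table(trees)
  infos <- precompute_treeinfo(trees)
  if (is.null(U)) U <- lt$labels
  U <- sort(as.character(U))
  miss <- setdiff(U, lt$labels)
  if (length(miss) > 0L) stop("taxa not in any tree: ", paste(miss, collapse = ", "))
  cw <- cross_witnesses(lt)
  S <- match(U, lt$labels)
  edges <- bwd_edges(infos, lt, cw, U, S)
  df <- data.frame(x = U[edges$from], y = U[edges$to],
                   provenance = ifelse(edges$build, "build", "distance"),
                   stringsAsFactors = FALSE)
  attr(df, "vertices") <- U
  df
}

# Edge lists of the BWD graph over U (S = positions of U in lt$labels).
# Returns from/to (positions within U, from < to) and a 'build' flag.
bwd_edges <- function(infos, lt, cw, U, S) {
  nu <- length(U)
  cnt <- graph_counts(infos, U)
  buildE <- upper.tri(cnt$w) & cnt$w >= 1L
  crossE <- matrix(FALSE, nu, nu)
  for (a in seq_len(nu)) {
    Wx <- cw[[S[a]]]
    hit <- rowSums(Wx[S, S, drop = FALSE]) > 0   # over witnesses z in U
    crossE[a, ] <- crossE[a, ] | hit
  }
  crossE <- crossE | t(crossE)
  crossE <- crossE & upper.tri(crossE)
  anyE <- buildE | crossE
  idx <- which(anyE, arr.ind = TRUE)
  list(from = idx[, 1], to = idx[, 2], build = buildE[idx])
}

#' Bisection disconnection threshold of a weighted graph
#'
#' Finds the smallest edge weight theta such that deleting every edge of
#' weight at most theta disconnects the graph, and returns the resulting
#' components (singletons allowed; if all weights are equal the graph falls
#' apart into isolated vertices).
#'
#' @param graph A data frame with columns \code{x}, \code{y}, \code{weight}
#'   describing a connected undirected graph; vertices are taken from
#'   attribute \code{vertices} if present, else from the edge endpoints.
#' @return List with elements \code{theta} (numeric) and \code{components}
#'   (list of character vectors).
#' @examples
#' g <- data.frame(x = c("a", "b", "a", "a"), y = c("b", "c", "c", "d"),
#'                 weight = c(5, 5, 2, 1))
#' bisection_disconnect(g)  # theta 1, components {a,b,c} and {d}
#' @export
bisection_disconnect <- function(graph) {
  verts <- attr(graph, "vertices")
  if (is.null(verts)) verts <- sort(unique(c(graph$x, graph$y)))
  nu <- length(verts)
  if (nu < 3L) stop("graph must have at least 3 vertices")
  from <- match(graph$x, verts); to <- match(graph$y, verts)
  w <- graph$weight
  if (max(uf_components(nu, from, to)) != 1L)
    stop("graph is already disconnected")
  for (theta in sort(unique(w))) {
    keep <- w > theta
    comp <- uf_components(nu, from[keep], to[keep])
    if (max(comp) > 1L)
      return(list(theta = theta,
                  components = unname(split(verts, comp))))
  }
  stop("internal error: deleting all edges failed to disconnect")  # unreachable
}

#' Build-with-Distances (BWD) supertree
#'
#' Follows the Build recursion on the BWD graph: connected components become
#' the children of the current node. When the graph over the current clade U
#' is connected, edges are weighted with the chosen support function (SAC or
#' SACmax) evaluated over U, the bisection threshold removes the weakest
#' edges, and the recursion continues on the resulting components. The
#' output is always plenary; unlike MC/MMC, BWD does not guarantee to return
#' a displaying tree on compatible inputs, because distance signal may
#' overrule topology.
#'
#' @param trees Nonempty list of rooted \code{"phylo"} trees with branch
#'   lengths.
#' @param support \code{"sac"} (default) or \code{"sacmax"}.
#' @return A \code{"phylo"} supertree on the union of leaf sets.
#' @examples
#' tr <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
#' write_newick(bwd_supertree(list(tr)))
#' @export
bwd_supertree <- function(trees, support = c("sac", "sacmax")) {
  support <- match.arg(support)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lt <- lambda_table(trees)
  infos <- precompute_treeinfo(trees)
  cw <- cross_witnesses(lt)
  frag <- bwd_recurse(infos, lt, cw, lt$labels, support)
  finish_newick(frag)
}

bwd_recurse <- function(infos, lt, cw, U, support) {
  nu <- length(U)
  if (nu == 1L) return(leaf_fragment(U))
  if (nu == 2L) return(combine_children(lapply(U, leaf_fragment)))
  S <- match(U, lt$labels)
  e <- bwd_edges(infos, lt, cw, U, S)
  comp <- uf_components(nu, e$from, e$to)
  if (max(comp) == 1L) {
    w <- sac_edge_weights(lt, U, S, e$from, e$to,
                          use_max = (support == "sacmax"))
    theta_comp <- bisect_positions(nu, e$from, e$to, w)
    comp <- theta_comp
  }
  children <- lapply(split(U, comp), function(sub) {
    bwd_recurse(infos, lt, cw, sub, support)
  })
  combine_children(children)
}

# Support weights for an edge list over clade U, vectorized over witnesses z.
sac_edge_weights <- function(lt, U, S, from, to, use_max) {
  lam <- lt$lambda[S, S, drop = FALSE]
  co <- lt$cooccur[S, S, drop = FALSE] >= 1L
  nu <- length(U)
  vapply(seq_along(from), function(k) {
    a <- from[k]; b <- to[k]
    zs <- setdiff(seq_len(nu), c(a, b))
    pab <- pz(lam, co, a, b, zs)
    pba <- pz(lam, co, b, a, zs)
    sum(if (use_max) pmax(pab, pba) else pmin(pab, pba))
  }, numeric(1))
}

pz <- function(lam, co, a, b, zs) {
  if (!co[a, b]) return(rep(0, length(zs)))
  p <- pmax(0, lam[a, zs] - lam[a, b])
  p[!co[a, zs] | is.na(p)] <- 0
  p
}

# bisection over integer vertex positions; returns component ids.
# Disconnection is monotone in the threshold, so the minimal disconnecting
# weight is found by binary search over the sorted distinct weights.
bisect_positions <- function(nu, from, to, w) {
  ws <- sort(unique(w))
  lo <- 1L; hi <- length(ws)   # invariant: removing <= ws[hi] disconnects
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    keep <- w > ws[mid]
    if (max(uf_components(nu, from[keep], to[keep])) > 1L) hi <- mid
    else lo <- mid + 1L
  }
  keep <- w > ws[lo]
  uf_components(nu, from[keep], to[keep])
}
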