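# Shared fixtures and independent oracles, built in code.

nwk <- function(s) parse_newick(s)

# random rooted binary tree with branch lengths in (0, 1]
rand_tree <- function(n, lengths = TRUE) {
  tr <- ape::rtree(n, rooted = TRUE)
  if (!lengths) tr$edge.length <- NULL
  tr
}

# caterpillar tree over labels in the given order (first two form the
# deepest cherry)
caterpillar <- function(labels) {
  s <- paste0("(", labels[1], ",", labels[2], ")")
  for (l in labels[-(1:2)]) s <- paste0("(", s, ",", l, ")")
  parse_newick(paste0(s, ";"))
}

# --- exhaustive enumeration of rooted binary topologies ------------------
# grow trees by inserting each new leaf on every edge (including above the
# root); n leaves yield (2n-3)!! topologies

all_rooted_binary_trees <- local({
  cache <- list()
  insert_everywhere <- function(node, x) {
    out <- list(list(node, x))               # above this subtree
    if (!is.character(node)) {
      for (ins in insert_everywhere(node[[1]], x))
        out <- c(out, list(list(ins, node[[2]])))
      for (ins in insert_everywhere(node[[2]], x))
        out <- c(out, list(list(node[[1]], ins)))
    }
    out
  }
  node_newick <- function(node) {
    if (is.character(node)) return(node)
    paste0("(", node_newick(node[[1]]), ",", node_newick(node[[2]]), ")")
  }
  function(labels) {
    key <- paste(labels, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    trees <- list(labels[1])
    for (x in labels[-1]) {
      trees <- unlist(lapply(trees, insert_everywhere, x = x),
                      recursive = FALSE)
    }
    res <- lapply(trees, function(t) parse_newick(paste0(node_newick(t), ";")))
    cache[[key]] <<- res
    res
  }
})

# triplet tables of all rooted binary topologies on canonical labels,
# memoized by leaf count
canon_triplet_tables <- local({
  cache <- list()
  function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    trees <- all_rooted_binary_trees(paste0("L", seq_len(k)))
    res <- lapply(trees, tree_triplets)
    cache[[key]] <<- list(trees = trees, triplets = res)
  }
})

# Independent compatibility oracle: a collection is compatible iff some
# rooted binary tree on the union of leaves contains every input triplet
# (restriction refines each input). Inputs are relabeled onto canonical
# labels so the enumerated tables can be reused.
brute_force_compatible <- function(trees) {
  u <- sort(unique(unlist(lapply(trees, leaf_labels))))
  k <- length(u)
  canon <- paste0("L", seq_len(k))
  need <- unlist(lapply(trees, function(tr) {
    tr$tip.label <- canon[match(tr$tip.label, u)]
    tree_triplets(tr)
  }))
  tab <- canon_triplet_tables(k)
  for (tt in tab$triplets) {
    if (all(need %in% tt)) return(TRUE)
  }
  FALSE
}

# Brute-force rooted MAST: maximize over all leaf subsets of the common
# leaf set the size for which both restrictions have identical clade sets.
brute_force_mast <- function(t1, t2) {
  common <- sort(intersect(t1$tip.label, t2$tip.label))
  n <- length(common)
  best <- min(n, 2L)                 # any 1- or 2-leaf subset agrees
  if (n < 3L) return(min(n, best))
  for (size in n:3) {
    if (size <= best) break
    subs <- utils::combn(common, size, simplify = FALSE)
    for (s in subs) {
      a <- restrict_tree(t1, s); b <- restrict_tree(t2, s)
      if (setequal(polysup:::clade_keys(a), polysup:::clade_keys(b))) {
        best <- size
        break
      }
    }
    if (best == size) break
  }
  best
}

# a random collection of small input trees for compatibility testing
rand_instance <- function(max_taxa = 6L) {
  n <- sample(4:max_taxa, 1)
  labs <- paste0("t", seq_len(n))
  ntrees <- sample(2:3, 1)
  trees <- lapply(seq_len(ntrees), function(i) {
    sz <- sample(3:n, 1)
    sub <- sample(labs, sz)
    tr <- rand_tree(sz)
    tr$tip.label <- sub
    tr$edge.length <- NULL
    tr
  })
  trees
}
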