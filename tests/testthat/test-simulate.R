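test_that("Yule trees are binary, labeled, and reproducible", {
  tr <- yule_tree(48, seed = 1)
  expect_length(tr$tip.label, 48)
  expect_length(tree_clades(tr), 46)
  expect_equal(tree_resolution(tr), 1)
  expect_identical(write_newick(yule_tree(20, seed = 9)),
                   write_newick(yule_tree(20, seed = 9)))
  expect_error(yule_tree(2), "at least 3")
})

test_that("branch rate deviation multiplies by truncated normals", {
  tr <- yule_tree(30, seed = 2)
  unit <- tr; unit$edge.length <- rep(1, nrow(tr$edge))
  dev <- deviate_rates(unit, tree_wide_rate = 1, seed = 3)
  expect_true(all(dev$edge.length >= 0.1 & dev$edge.length <= 2.0))

  zero <- deviate_rates(unit, tree_wide_rate = 0, seed = 3)
  expect_true(all(zero$edge.length == 0))

  # default tree-wide rate targets mean root-to-leaf length 0.3
  dv <- deviate_rates(tr, seed = 4)
  depths <- ape::node.depth.edgelength(dv)[seq_along(dv$tip.label)]
  expect_equal(mean(depths), 0.3, tolerance = 1e-9)
})

test_that("the rate multiplier mean matches the truncated-normal oracle", {
  # oracle: E[R] for Normal(1, 0.5) conditioned on [0.1, 2.0], by quadrature
  f <- function(x) x * stats::dnorm(x, 1, 0.5)
  z <- stats::pnorm(2, 1, 0.5) - stats::pnorm(0.1, 1, 0.5)
  mu <- stats::integrate(f, 0.1, 2)$value / z
  set.seed(5)
  draws <- polysup:::draw_branch_rates(1e5)
  expect_true(all(draws >= 0.1 & draws <= 2))
  expect_equal(mean(draws), mu, tolerance = 0.01)
})

test_that("outgroup attachment uses 1.25 x d_max and is invertible", {
  set.seed(6)
  tr <- deviate_rates(yule_tree(12), seed = 7)
  D <- ape::cophenetic.phylo(tr)
  d_max <- max(D[which.max(rowSums(D)), ])
  og <- add_outgroup(tr, "OG")
  expect_length(og$tip.label, 13)
  # the outgroup pendant edge hangs off the new root
  og_edge <- og$edge.length[og$edge[, 2] == match("OG", og$tip.label)]
  expect_equal(og_edge, 1.25 * d_max, tolerance = 1e-9)
  # pruning the outgroup recovers the original distances
  back <- restrict_tree(og, tr$tip.label)
  labs <- sort(tr$tip.label)
  expect_equal(ape::cophenetic.phylo(back)[labs, labs], D[labs, labs],
               tolerance = 1e-9)
  expect_error(add_outgroup(og, "OG"), "already occurs")
})

test_that("taxon deletion respects the ratio and keeps the outgroup", {
  set.seed(8)
  tr <- add_outgroup(deviate_rates(yule_tree(48), seed = 8), "OG")
  del <- delete_taxa(tr, 0.25, keep = "OG", seed = 9)
  expect_length(setdiff(del$tip.label, "OG"), 36)
  expect_true("OG" %in% del$tip.label)
  ident <- delete_taxa(tr, 0, keep = "OG", seed = 9)
  expect_setequal(ident$tip.label, tr$tip.label)
  expect_error(delete_taxa(tr, 1.0, keep = "OG"), "ratio")
})

test_that("the GTR rate matrix is reversible with unit mean rate", {
  p <- gtr_params()
  expect_equal(sum(p$base_freq), 1)
  Q <- gtr_rate_matrix(p)
  expect_equal(rowSums(Q), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  S <- diag(p$base_freq) %*% Q
  expect_equal(unname(S), unname(t(S)), tolerance = 1e-12)
  expect_equal(-sum(p$base_freq * diag(Q)), 1, tolerance = 1e-12)
  expect_error(gtr_params(base_freq = c(0.5, 0.5, 0.2, 0.2)), "summing")
  expect_error(gtr_params(p_invar = 1), "p_invar")
})

test_that("discrete gamma categories have unit mean rate", {
  r <- discrete_gamma_rates(1.1999, 4)
  expect_length(r, 4)
  expect_equal(mean(r), 1, tolerance = 1e-9)
  expect_true(all(diff(r) > 0))
})

test_that("sequence evolution respects invariant sites and stationarity", {
  tr <- nwk("(a:0.2,b:0.2);")
  # p_invar near 1: all sequences identical to the root draw
  aln <- evolve_sequences(tr, 200, params = gtr_params(p_invar = 0.999999),
                          seed = 10)
  expect_true(all(aln["a", ] == aln["b", ]))

  # base composition at stationarity
  p <- gtr_params()
  long <- nwk("(a:8,b:8);")
  aln2 <- evolve_sequences(long, 20000, params = p, seed = 11)
  freq <- table(factor(as.vector(aln2), levels = c("a", "c", "g", "t")))
  expect_equal(as.numeric(freq / sum(freq)), p$base_freq, tolerance = 0.02)

  # determinism under a fixed seed
  expect_identical(evolve_sequences(tr, 50, seed = 12),
                   evolve_sequences(tr, 50, seed = 12))
})

test_that("the NJ stand-in recovers easy topologies deterministically", {
  # 4-taxon tree with a long internal branch plus outgroup
  tr <- nwk("(((a:0.05,b:0.05):0.3,(c:0.05,d:0.05):0.3):0.1,OG:1);")
  aln <- evolve_sequences(tr, 2000, seed = 13)
  rec <- nj_tree(aln, "OG")
  expect_setequal(rec$tip.label, c("a", "b", "c", "d"))
  expect_setequal(polysup:::clade_keys(rec),
                  polysup:::clade_keys(nwk("((a,b),(c,d));")))
  expect_true(all(rec$edge.length >= 0))

  # row order does not matter
  perm <- aln[sample(nrow(aln)), , drop = FALSE]
  expect_equal(write_newick(nj_tree(perm, "OG")), write_newick(rec))

  expect_error(nj_tree(aln[1:2, ], "OG"), "at least 3")
  expect_error(nj_tree(aln, "nope"), "not found")
})

test_that("replicate generation covers all modes and is reproducible", {
  cfg <- sim_config(n_taxa = 12, deletion_ratio = 0.25, n_input_trees = 4,
                    input_mode = "clean_restriction", seed = 14)
  sim <- make_input_trees(cfg)
  expect_length(sim$inputs, 4)
  expect_length(sim$model$tip.label, 12)
  expect_length(sim$model_outgroup$tip.label, 13)
  for (tr in sim$inputs) {
    expect_length(tr$tip.label, 9)     # 12 - floor(0.25 * 12)
    expect_true(displays(sim$model, tr))
  }
  # clean restrictions are always compatible with each other
  expect_false(is_incompatible(build_supertree(sim$inputs)))

  sim2 <- make_input_trees(cfg)
  expect_identical(lapply(sim$inputs, write_newick),
                   lapply(sim2$inputs, write_newick))

  nni <- make_input_trees(sim_config(n_taxa = 10, deletion_ratio = 0.2,
                                     n_input_trees = 3,
                                     input_mode = "nni_perturb", seed = 15))
  expect_length(nni$inputs, 3)

  seqm <- make_input_trees(sim_config(n_taxa = 10, deletion_ratio = 0.2,
                                      n_input_trees = 3,
                                      input_mode = "sequence_nj", seed = 16))
  for (tr in seqm$inputs) {
    expect_length(tr$tip.label, 8)
    expect_false("OG" %in% tr$tip.label)
    expect_false(is.null(tr$edge.length))
  }
})

test_that("unrooted topology counts follow the double factorial", {
  expect_equal(count_unrooted_trees(3)$exact, "1")
  expect_equal(count_unrooted_trees(4)$exact, "3")
  # recurrence N(n) = N(n-1) * (2n - 5), exactly representable up to n = 17
  acc <- 3
  for (n in 5:17) {
    acc <- acc * (2 * n - 5)
    expect_equal(count_unrooted_trees(n)$exact, sprintf("%.0f", acc))
  }
  # magnitude path agrees with the exact decimal representation for larger n
  for (n in c(50, 200, 500)) {
    ct <- count_unrooted_trees(n)
    lg_exact <- (nchar(ct$exact) - 1) +
      log10(as.numeric(substr(ct$exact, 1, 9)) / 1e8)
    expect_equal(ct$exponent + log10(ct$mantissa), lg_exact,
                 tolerance = 0.025)
  }
  expect_error(count_unrooted_trees(2), "at least 3")
})
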