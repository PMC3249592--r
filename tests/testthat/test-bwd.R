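same_topology <- function(a, b) {
  setequal(leaf_labels(a), leaf_labels(b)) &&
    setequal(polysup:::clade_keys(a), polysup:::clade_keys(b))
}

test_that("the lambda table averages distances to the lca and is asymmetric", {
  lt <- lambda_table(list(nwk("((a:1,b:2):1,c:4);")))
  expect_equal(lt$lambda["a", "b"], 1)
  expect_equal(lt$lambda["b", "a"], 2)
  expect_equal(lt$lambda["a", "c"], 2)
  expect_equal(lt$lambda["c", "a"], 4)

  two <- lambda_table(list(nwk("((a:1,b:1):1,c:1);"),
                           nwk("((a:3,b:1):1,c:1);")))
  expect_equal(two$lambda["a", "b"], 2)  # mean of 1 and 3

  disj <- lambda_table(list(nwk("(a:1,b:1);"), nwk("(c:1,d:1);")))
  expect_true(is.na(disj$lambda["a", "c"]))
  expect_equal(disj$cooccur["a", "c"], 0L)

  expect_error(lambda_table(list(nwk("((a,b),c);"))), "branch lengths")
})

test_that("primary evidence is the clamped lambda difference", {
  lt <- lambda_table(list(nwk("((a:1,b:2):1,c:4);")))
  expect_equal(primary_evidence(lt, "a", "b", "c"), 1)
  expect_equal(primary_evidence(lt, "a", "c", "b"), 0)  # clamped at zero
  expect_error(primary_evidence(lt, "a", "a", "c"), "distinct")

  disj <- lambda_table(list(nwk("(a:1,b:1);"), nwk("(c:1,d:1);")))
  expect_equal(primary_evidence(disj, "a", "b", "c"), 0)  # no cooccurrence
})

test_that("SAC and SACmax agree with hand evaluation and their ordering", {
  lt <- lambda_table(list(nwk("((a:1,b:2):1,c:4);")))
  U <- c("a", "b", "c")
  expect_equal(support_sac(lt, "a", "b", U), 1)
  expect_equal(support_sac_max(lt, "a", "b", U), 1)
  expect_equal(support_sac(lt, "a", "b", U), support_sac(lt, "b", "a", U))

  set.seed(91)
  for (i in 1:5) {
    trees <- lapply(1:3, function(j) rand_tree(6))
    lt2 <- lambda_table(trees)
    U2 <- lt2$labels
    pair <- sample(U2, 2)
    s <- support_sac(lt2, pair[1], pair[2], U2)
    smax <- support_sac_max(lt2, pair[1], pair[2], U2)
    expect_gte(s, 0)
    expect_lte(s, smax + 1e-12)
    expect_equal(s, support_sac(lt2, pair[2], pair[1], U2))
  }
})

test_that("the BWD graph adds cross-tree distance edges", {
  # two cherries sharing only x: distance evidence links x with the closer leaf
  trees <- list(nwk("(x:1,y:1);"), nwk("(x:5,z:5);"))
  g <- bwd_graph(trees)
  expect_equal(nrow(g), 1L)
  expect_setequal(c(g$x, g$y), c("x", "y"))
  expect_equal(g$provenance, "distance")

  # equal lambdas: strict inequality fails, no edge
  geq <- bwd_graph(list(nwk("(x:1,y:1);"), nwk("(x:1,z:1);")))
  expect_equal(nrow(geq), 0L)

  # a single input tree contributes no cross edges
  tr <- nwk("(((a:1,b:1):1,c:2):1,d:3);")
  g1 <- bwd_graph(list(tr))
  expect_true(all(g1$provenance == "build"))
  g1b <- taxon_graph(list(tr))
  expect_setequal(paste(g1$x, g1$y), paste(g1b$x, g1b$y))
})

test_that("bisection finds the minimal disconnecting threshold", {
  g <- data.frame(x = c("a", "b", "a", "a"), y = c("b", "c", "c", "d"),
                  weight = c(5, 5, 2, 1))
  r <- bisection_disconnect(g)
  expect_equal(r$theta, 1)
  expect_equal(sort(vapply(r$components, paste, character(1),
                           collapse = "")), c("abc", "d"))

  tri <- data.frame(x = c("a", "a", "b"), y = c("b", "c", "c"),
                    weight = c(5, 5, 5))
  rt <- bisection_disconnect(tri)
  expect_equal(rt$theta, 5)
  expect_length(rt$components, 3)

  path <- data.frame(x = c("a", "b"), y = c("b", "c"), weight = c(3, 7))
  rp <- bisection_disconnect(path)
  expect_equal(rp$theta, 3)

  disc <- data.frame(x = "a", y = "b", weight = 1)
  attr(disc, "vertices") <- c("a", "b", "c")
  expect_error(bisection_disconnect(disc), "already disconnected")
})

test_that("BWD returns a single binary input tree unchanged", {
  set.seed(101)
  for (n in c(5, 8, 12, 16)) {
    tr <- rand_tree(n)
    expect_true(same_topology(bwd_supertree(list(tr)), tr))
    expect_true(same_topology(bwd_supertree(list(tr, tr)), tr))
  }
})

test_that("BWD output is plenary and scaling-invariant", {
  set.seed(111)
  for (i in 1:4) {
    model <- rand_tree(10)
    inputs <- lapply(1:3, function(j)
      restrict_tree(model, sample(model$tip.label, 7)))
    st <- bwd_supertree(inputs)
    expect_setequal(leaf_labels(st), sort(unique(unlist(lapply(inputs,
                                                               leaf_labels)))))
    scaled <- lapply(inputs, apply_constant, c = 7.3)
    expect_true(same_topology(bwd_supertree(scaled), st))
    expect_true(same_topology(bwd_supertree(inputs, support = "sacmax"),
                              bwd_supertree(scaled, support = "sacmax")))
  }
})

test_that("clean full-coverage restrictions reproduce the model topology", {
  set.seed(121)
  model <- rand_tree(9)
  inputs <- lapply(1:6, function(j)
    restrict_tree(model, sample(model$tip.label, 7)))
  covered_pairs <- TRUE
  u <- model$tip.label
  for (a in u) for (b in u) if (a < b) {
    if (!any(vapply(inputs, function(tr)
      all(c(a, b) %in% tr$tip.label), TRUE))) covered_pairs <- FALSE
  }
  expect_true(covered_pairs)  # seed chosen large enough to cover all pairs
  st <- bwd_supertree(inputs)
  expect_equal(triplet_comparison(model, st)$d_tr, 0)
})
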