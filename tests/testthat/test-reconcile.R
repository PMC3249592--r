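dm <- function(labels, values) {
  # symmetric matrix from upper-triangle values in row-major pair order
  n <- length(labels)
  M <- matrix(0, n, n, dimnames = list(labels, labels))
  M[upper.tri(M)] <- NA
  k <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <- values[k]; k <- k + 1
  }
  M
}

test_that("tree distance matrices are path-length sums", {
  D <- tree_distance_matrix(nwk("((a:1,b:2):1,c:2);"))
  expect_equal(D["a", "b"], 3)
  expect_equal(D["a", "c"], 4)
  expect_equal(D["b", "c"], 5)
  expect_true(all(diag(D) == 0))
  expect_equal(D, t(D))
  expect_equal(tree_distance_matrix(nwk("(a:1,b:1);"))["a", "b"], 2)
})

test_that("the trimmed mean recovers the scale constant robustly", {
  labs <- letters[1:4]
  D_T <- dm(labs, c(1, 2, 3, 4, 5, 6))
  expect_equal(trimmed_mean_constant(2 * D_T, D_T), 2)
  expect_equal(trimmed_mean_constant(2 * D_T, D_T, alpha = 0), 2)
  expect_equal(trimmed_mean_constant(2 * D_T, D_T, alpha = 0.49), 2)

  # alpha = 0 is the plain mean
  D1 <- dm(c("a", "b"), 1); D2 <- dm(c("a", "b"), 1)
  expect_equal(trimmed_mean_constant(dm(c("a", "b"), 3), dm(c("a", "b"), 1),
                                     alpha = 0), 3)

  # m = 10 ratios, three corrupted per tail, middle all 2
  labs5 <- letters[1:5]
  D_T5 <- dm(labs5, rep(1, 10))
  vals <- c(2, 2, 2, 2, 2, 2, 2, 100, 0.01, 2)
  expect_equal(trimmed_mean_constant(dm(labs5, vals), D_T5), 2)

  expect_error(trimmed_mean_constant(D_T, D_T, alpha = 0.5), "alpha")
})

test_that("trimmed mean tolerates up to floor(alpha*m) corruptions per tail", {
  set.seed(131)
  for (i in 1:5) {
    labs <- paste0("t", 1:6)                 # m = 15 pairs
    D_T <- dm(labs, runif(15, 1, 3))
    c_true <- runif(1, 0.5, 4)
    D <- c_true * D_T
    m <- 15; k <- floor(m / 3)               # alpha = 1/3 -> 5 per tail
    pairs <- which(upper.tri(D_T), arr.ind = TRUE)
    up <- sample(nrow(pairs), 2 * k)
    hi <- up[seq_len(k)]; lo <- up[-seq_len(k)]
    for (p in hi) { i1 <- pairs[p, 1]; j1 <- pairs[p, 2]
      D[i1, j1] <- D[j1, i1] <- D[i1, j1] * 1e3 }
    for (p in lo) { i1 <- pairs[p, 1]; j1 <- pairs[p, 2]
      D[i1, j1] <- D[j1, i1] <- D[i1, j1] * 1e-3 }
    expect_equal(trimmed_mean_constant(D, D_T), c_true, tolerance = 1e-10)
  }
})

test_that("least squares uses the closed-form minimizer", {
  labs <- c("a", "b", "c")
  # pairs (a,b) and (a,c) carry the signal; third pair set equal to fit
  D_T <- dm(labs, c(1, 2, 3))
  expect_equal(least_squares_constant(dm(labs, c(2, 4, 6)), D_T), 2)
  D <- dm(labs, c(2, 4.2, 6))
  expect_equal(least_squares_constant(D, D_T), (2 + 8.4 + 18) / 14)
  expect_equal(least_squares_constant(dm(c("a", "b"), 6), dm(c("a", "b"), 3)),
               2)
  # differs from the untrimmed ratio mean unless all ratios are equal
  expect_false(isTRUE(all.equal(
    least_squares_constant(D, D_T),
    trimmed_mean_constant(D, D_T, alpha = 0))))
})

test_that("the minimax constant balances the extreme residuals", {
  labs <- c("a", "b", "c")
  D_T <- dm(labs, c(1, 2, 3))
  expect_equal(minimax_constant(2 * D_T, D_T), 2, tolerance = 1e-9)
  # two unit pairs at 1 and 3: optimum at 2 with objective 1
  D_T2 <- dm(labs, c(1, 1, 1e-9))
  D2 <- dm(labs, c(1, 3, 2e-9))
  expect_equal(minimax_constant(D2, D_T2), 2, tolerance = 1e-6)
  expect_equal(minimax_constant(dm(c("a", "b"), 6), dm(c("a", "b"), 3)), 2)
})

test_that("minimax matches a grid-refinement oracle", {
  set.seed(141)
  for (i in 1:6) {
    labs <- paste0("t", 1:5)
    D_T <- dm(labs, runif(10, 0.5, 3))
    D <- dm(labs, runif(10, 0.5, 6))
    c_hat <- minimax_constant(D, D_T)
    d <- D[upper.tri(D)]; dt <- D_T[upper.tri(D_T)]
    obj <- function(c) max(abs(d - c * dt))
    # independent oracle: iterative grid refinement
    lo <- 0; hi <- max(d / dt) + 1
    for (pass in 1:8) {
      grid <- seq(lo, hi, length.out = 201)
      vals <- vapply(grid, obj, numeric(1))
      best <- which.min(vals)
      lo <- grid[max(1, best - 1)]; hi <- grid[min(201, best + 1)]
    }
    c_star <- (lo + hi) / 2
    expect_lte(obj(c_hat), obj(c_star) + 1e-9)
    expect_equal(c_hat, c_star, tolerance = 1e-5)
  }
})

test_that("applying constants rescales lengths and composes to identity", {
  tr <- nwk("((a:1,b:2):1,c:2);")
  expect_equal(apply_constant(tr, 1)$edge.length, tr$edge.length)
  expect_equal(path_length(apply_constant(tr, 2), "a", "b"), 6)
  back <- apply_constant(apply_constant(tr, 2), 0.5)
  expect_equal(back$edge.length, tr$edge.length)
  expect_error(apply_constant(tr, 0), "c")
})

test_that("reconcile_trees rescales each tree by its own constant", {
  set.seed(151)
  ref <- rand_tree(8)
  D <- tree_distance_matrix(ref)
  trees <- list(apply_constant(restrict_tree(ref, sort(ref$tip.label)[1:6]), 3),
                apply_constant(restrict_tree(ref, sort(ref$tip.label)[3:8]), 0.25))
  out <- reconcile_trees(trees, D, method = "trimmed")
  expect_equal(unname(attr(out, "constants")), c(1 / 3, 4), tolerance = 1e-9)
  for (k in 1:2) {
    Dk <- tree_distance_matrix(out[[k]])
    expect_equal(Dk, D[rownames(Dk), colnames(Dk)], tolerance = 1e-9)
  }
})
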