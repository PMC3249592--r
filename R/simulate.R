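#' Yule (pure-birth) model tree
#'
#' Generates a rooted binary tree with \code{n} leaves labeled
#' \code{t1..tn} under a unit-rate pure-birth process; branch lengths are
#' the branch durations of the process.
#'
#' @param n Number of leaves (at least 3).
#' @param seed Optional integer seed for reproducibility.
#' @return A binary \code{"phylo"} tree.
#' @export
yule_tree <- function(n, seed = NULL) {
  if (n < 3L) stop("'n' must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  ape::rphylo(n, birth = 1, death = 0)
}

# truncated-normal multiplier by rejection: Normal(1, 0.5) redrawn until
# inside [0.1, 2.0]
draw_branch_rates <- function(k) {
  out <- numeric(k)
  need <- seq_len(k)
  while (length(need) > 0L) {
    r <- stats::rnorm(length(need), mean = 1, sd = 0.5)
    ok <- r >= 0.1 & r <= 2.0
    out[need[ok]] <- r[ok]
    need <- need[!ok]
  }
  out
}

#' Deviate branch rates away from a molecular clock
#'
#' Multiplies every branch duration by an independent rate drawn from a
#' Normal(1.0, 0.5) truncated to \[0.1, 2.0\] (redrawn until inside), times
#' an overall tree-wide substitution rate. With the default
#' \code{tree_wide_rate = NULL} the tree-wide rate is chosen so the mean
#' root-to-leaf path of the resulting tree is 0.3 expected
#' substitutions/site.
#'
#' @param tree A \code{"phylo"} tree whose branch lengths are durations.
#' @param tree_wide_rate Overall rate multiplier, or \code{NULL} to target a
#'   mean root-to-leaf length of 0.3.
#' @param seed Optional integer seed.
#' @return The tree with branch lengths duration * branch rate * tree rate.
#' @export
deviate_rates <- function(tree, tree_wide_rate = NULL, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch durations")
  if (!is.null(seed)) set.seed(seed)
  r <- draw_branch_rates(nrow(tree$edge))
  tree$edge.length <- tree$edge.length * r
  if (is.null(tree_wide_rate)) {
    depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
    md <- mean(depths)
    tree_wide_rate <- if (md > 0) 0.3 / md else 0
  }
  tree$edge.length <- tree$edge.length * tree_wide_rate
  tree
}

#' Attach an outgroup taxon below a new root
#'
#' Identifies the taxon with the largest total distance to all others and
#' takes d_max as its largest pairwise distance. If d_max exceeds the
#' second-largest per-taxon maximum distance by more than 75\%, the pendant
#' branch of that taxon is shortened until the excess is exactly 75\%
#' (d_max recomputed afterwards). A new root is then created with the old
#' root (connecting branch of length 0) and the outgroup as children, the
#' outgroup pendant branch being 1.25 * d_max.
#'
#' @param tree A \code{"phylo"} tree with branch lengths.
#' @param label Outgroup leaf label (must not already occur in the tree).
#' @return A \code{"phylo"} tree with \code{n + 1} leaves.
#' @export
add_outgroup <- function(tree, label = "OG") {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (label %in% tree$tip.label)
    stop("outgroup label '", label, "' already occurs in the tree")
  D <- ape::cophenetic.phylo(tree)
  tot <- rowSums(D)
  far <- which.max(tot)
  taxmax <- apply(D, 1L, max)
  second <- max(taxmax[-far])
  if (taxmax[far] > 1.75 * second) {
    excess <- taxmax[far] - 1.75 * second
    tip_id <- match(names(far), tree$tip.label)
    eidx <- which(tree$edge[, 2] == tip_id)
    newlen <- tree$edge.length[eidx] - excess
    if (newlen < 0) newlen <- 0
    tree$edge.length[eidx] <- newlen
    D <- ape::cophenetic.phylo(tree)
  }
  d_max <- max(D[which.max(rowSums(D)), ])
  core <- sub(";$", "", ape::write.tree(tree, digits = 17))
  parse_newick(sprintf("(%s:0,%s:%.17g);", core, label, 1.25 * d_max))
}

# kept labels after deleting floor(ratio * |ingroup|) ingroup taxa at random
sample_kept <- function(labels, ratio, keep = character(0)) {
  ingroup <- setdiff(labels, keep)
  ndel <- floor(ratio * length(ingroup))
  kept <- c(setdiff(ingroup, sample(ingroup, ndel)), keep)
  if (length(kept) < 3L)
    stop("taxon deletion leaves fewer than 3 taxa")
  sort(kept)
}

#' Randomly delete taxa from a tree
#'
#' Removes a uniformly random subset of \code{floor(ratio * n)} non-outgroup
#' taxa (n counting only non-outgroup taxa) and returns the restriction of
#' the tree to the remainder. Taxa listed in \code{keep} (typically the
#' outgroup) are always retained.
#'
#' @param tree A \code{"phylo"} tree.
#' @param ratio Deletion fraction in \[0, 1).
#' @param keep Labels never deleted.
#' @param seed Optional integer seed.
#' @return The restricted \code{"phylo"} tree.
#' @export
delete_taxa <- function(tree, ratio, keep = character(0), seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (ratio < 0 || ratio >= 1) stop("'ratio' must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  restrict_tree(tree, sample_kept(tree$tip.label, ratio, keep))
}

#' GTR+Gamma+I substitution model parameters
#'
#' Defaults follow a published parameter set for empirical alignments:
#' stationary frequencies (A, C, G) = (0.3468, 0.3594, 0.0805) with T as the
#' complement (0.2133), exchangeabilities (AC, AG, AT, CG, CT) =
#' (0.6750, 27.9597, 1.1677, 0.4547, 20.8760) with GT = 1, gamma shape
#' 1.1999, and invariant-site proportion 0.4954.
#'
#' @param base_freq Stationary frequencies (A, C, G, T), positive, summing
#'   to 1.
#' @param rates Six exchangeabilities (AC, AG, AT, CG, CT, GT), positive.
#' @param gamma_shape Shape of the gamma rate-heterogeneity distribution.
#' @param p_invar Proportion of invariant sites in \[0, 1).
#' @return An object of class \code{"gtr_params"}.
#' @export
gtr_params <- function(base_freq = c(0.3468, 0.3594, 0.0805, 0.2133),
                       rates = c(0.6750, 27.9597, 1.1677, 0.4547, 20.8760, 1),
                       gamma_shape = 1.1999, p_invar = 0.4954) {
  if (length(base_freq) != 4L || any(base_freq <= 0) ||
      abs(sum(base_freq) - 1) > 1e-6)
    stop("'base_freq' must be 4 positive values summing to 1")
  if (length(rates) != 6L || any(rates <= 0))
    stop("'rates' must be 6 positive exchangeabilities")
  if (gamma_shape <= 0) stop("'gamma_shape' must be > 0")
  if (p_invar < 0 || p_invar >= 1) stop("'p_invar' must be in [0, 1)")
  structure(list(base_freq = base_freq / sum(base_freq), rates = rates,
                 gamma_shape = gamma_shape, p_invar = p_invar),
            class = "gtr_params")
}

#' GTR instantaneous rate matrix
#'
#' Builds the general time reversible rate matrix Q with q_ij proportional
#' to r_ij * pi_j, rows summing to zero, normalized so the expected number
#' of substitutions per unit branch length at stationarity is 1. Satisfies
#' detailed balance pi_i q_ij = pi_j q_ji.
#'
#' @param params A [gtr_params()] object.
#' @return A 4x4 numeric matrix with dimnames \code{c("a","c","g","t")}.
#' @export
gtr_rate_matrix <- function(params = gtr_params()) {
  stopifnot(inherits(params, "gtr_params"))
  bf <- params$base_freq
  r <- params$rates
  R <- matrix(0, 4, 4)
  R[lower.tri(R)] <- r  # fills (2,1)=AC, (3,1)=AG, (4,1)=AT, (3,2)=CG, ...
  R <- R + t(R)
  Q <- R * matrix(bf, 4, 4, byrow = TRUE)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(bf * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(c("a", "c", "g", "t"), c("a", "c", "g", "t"))
  Q
}

#' Mean rates of the discrete gamma approximation
#'
#' Mean rate of each of \code{k} equal-probability categories of a
#' Gamma(shape, shape) distribution (mean 1), the standard discrete
#' approximation for among-site rate heterogeneity.
#'
#' @param shape Gamma shape parameter.
#' @param k Number of categories.
#' @return Numeric vector of k category rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, k = 4L) {
  if (shape <= 0) stop("'shape' must be > 0")
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = shape,
                     rate = shape)
  means <- k * diff(stats::pgamma(b, shape = shape + 1, rate = shape))
  means / mean(means) * 1  # guard tiny numerical drift; mean is 1 by design
}

#' Simulate nucleotide sequences along a tree (GTR+Gamma+I)
#'
#' Each site is invariant with probability \code{p_invar} (identical in all
#' leaves, drawn from the stationary frequencies) or evolves under GTR with
#' a rate from one of \code{ncat} discrete gamma categories, scaled by
#' 1/(1 - p_invar) so the mean rate over all sites is 1 and branch lengths
#' read as expected substitutions per site.
#'
#' @param tree A \code{"phylo"} tree with branch lengths in expected
#'   substitutions/site.
#' @param length Alignment length in base pairs.
#' @param params A [gtr_params()] object.
#' @param ncat Number of discrete gamma categories.
#' @param seed Optional integer seed.
#' @return Character matrix (taxa x sites, lowercase bases) with taxa as
#'   rownames.
#' @export
evolve_sequences <- function(tree, length, params = gtr_params(), ncat = 4L,
                             seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!is.null(seed)) set.seed(seed)
  n <- base::length(tree$tip.label)
  bases <- c("a", "c", "g", "t")
  nsite <- as.integer(length)
  pinv <- params$p_invar
  gr <- discrete_gamma_rates(params$gamma_shape, ncat)
  # site classes: 0 = invariant, 1..ncat = gamma category
  cls <- sample.int(ncat + 1L, nsite, replace = TRUE,
                    prob = c(pinv, rep((1 - pinv) / ncat, ncat))) - 1L
  aln <- matrix("", n, nsite, dimnames = list(tree$tip.label, NULL))
  inv <- which(cls == 0L)
  if (base::length(inv) > 0L) {
    rootstate <- sample(bases, base::length(inv), replace = TRUE,
                        prob = params$base_freq)
    aln[, inv] <- matrix(rootstate, n, base::length(inv), byrow = TRUE)
  }
  for (j in seq_len(ncat)) {
    sites <- which(cls == j)
    if (base::length(sites) == 0L) next
    rate <- gr[j] / (1 - pinv)
    sim <- phangorn::simSeq(tree, l = base::length(sites),
                            Q = params$rates, bf = params$base_freq,
                            rate = rate)
    aln[, sites] <- as.character(sim)[tree$tip.label, , drop = FALSE]
  }
  aln
}

#' Neighbor-joining tree from an alignment, rooted by outgroup
#'
#' A deterministic stand-in for maximum-likelihood tree inference:
#' Jukes-Cantor corrected distances, neighbor joining, rooting on the
#' outgroup pendant branch, then pruning the outgroup. Negative NJ branch
#' lengths are clamped to zero. Taxa are processed in sorted label order so
#' the result does not depend on input row order.
#'
#' @param alignment Character matrix (taxa x sites) or \code{DNAbin}.
#' @param outgroup Label of the outgroup sequence (present in the
#'   alignment).
#' @return A rooted \code{"phylo"} tree on the non-outgroup taxa, with
#'   branch lengths.
#' @export
nj_tree <- function(alignment, outgroup) {
  if (inherits(alignment, "DNAbin")) alignment <- as.character(alignment)
  if (!is.matrix(alignment) || is.null(rownames(alignment)))
    stop("'alignment' must be a matrix with taxa as rownames")
  if (nrow(alignment) < 3L) stop("need at least 3 sequences")
  if (!outgroup %in% rownames(alignment))
    stop("outgroup '", outgroup, "' not found in alignment")
  alignment <- alignment[sort(rownames(alignment)), , drop = FALSE]
  p <- as.matrix(ape::dist.dna(ape::as.DNAbin(alignment), model = "raw",
                               pairwise.deletion = TRUE))
  if (any(!is.finite(p))) stop("degenerate distances (non-finite p-distance)")
  # Jukes-Cantor correction, capped just below the saturation singularity
  p <- pmin(p, 0.7499)
  d <- -0.75 * log(1 - 4 / 3 * p)
  tr <- ape::nj(as.dist(d))
  tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- restrict_tree(tr, setdiff(tr$tip.label, outgroup))
  tr
}

#' Simulation configuration
#'
#' Bundles the knobs of the benchmark generator. Block length defaults to
#' 1000 bp for up to 144 taxa and 500 bp beyond.
#'
#' @param n_taxa Number of ingroup taxa (>= 4).
#' @param deletion_ratio Fraction of ingroup taxa deleted per input tree.
#' @param n_input_trees Number of input trees per replicate (>= 2).
#' @param block_length Alignment block length per input tree (bp).
#' @param tree_wide_rate Overall substitution rate; \code{NULL} targets a
#'   mean root-to-leaf path of 0.3 substitutions/site.
#' @param input_mode \code{"sequence_nj"} (simulate a block, delete taxa,
#'   reconstruct by NJ), \code{"clean_restriction"} (exact restrictions of
#'   the model tree), or \code{"nni_perturb"} (restriction plus random NNI
#'   moves).
#' @param nni_moves Number of random NNI moves in \code{"nni_perturb"} mode.
#' @param gtr A [gtr_params()] object.
#' @param outgroup Outgroup label.
#' @param seed Integer seed recorded in the output.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_taxa = 96L, deletion_ratio = 0.5,
                       n_input_trees = 10L, block_length = NULL,
                       tree_wide_rate = NULL,
                       input_mode = c("sequence_nj", "clean_restriction",
                                      "nni_perturb"),
                       nni_moves = 2L, gtr = gtr_params(), outgroup = "OG",
                       seed = 1L) {
  input_mode <- match.arg(input_mode)
  if (n_taxa < 4L) stop("'n_taxa' must be at least 4")
  if (deletion_ratio < 0 || deletion_ratio >= 1)
    stop("'deletion_ratio' must be in [0, 1)")
  if (n_input_trees < 2L) stop("'n_input_trees' must be at least 2")
  if (is.null(block_length))
    block_length <- if (n_taxa <= 144L) 1000L else 500L
  structure(list(n_taxa = as.integer(n_taxa),
                 deletion_ratio = deletion_ratio,
                 n_input_trees = as.integer(n_input_trees),
                 block_length = as.integer(block_length),
                 tree_wide_rate = tree_wide_rate,
                 input_mode = input_mode, nni_moves = as.integer(nni_moves),
                 gtr = gtr, outgroup = outgroup, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a model tree and its input trees
#'
#' One benchmark replicate: draws a Yule model tree, deviates its branch
#' rates, attaches the outgroup, and produces \code{n_input_trees} input
#' trees, each from an independent random taxon deletion. Depending on
#' \code{input_mode} the input trees are exact restrictions of the model,
#' NJ reconstructions from an independently simulated GTR+Gamma+I alignment
#' block, or restrictions perturbed by random NNI moves.
#'
#' @param config A [sim_config()] object.
#' @return List with \code{model} (ingroup model tree),
#'   \code{model_outgroup} (model with outgroup attached), \code{inputs}
#'   (list of input trees, outgroup already pruned), \code{covered}
#'   (logical: do the input leaf sets cover all ingroup taxa?), and
#'   \code{config}.
#' @export
make_input_trees <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  model <- yule_tree(config$n_taxa)
  model <- deviate_rates(model, config$tree_wide_rate)
  model_og <- add_outgroup(model, config$outgroup)
  og <- config$outgroup
  inputs <- vector("list", config$n_input_trees)
  for (i in seq_len(config$n_input_trees)) {
    kept <- sample_kept(model$tip.label, config$deletion_ratio)
    inputs[[i]] <- switch(config$input_mode,
      clean_restriction = restrict_tree(model, kept),
      nni_perturb = {
        tr <- restrict_tree(model, kept)
        if (config$nni_moves > 0L) tr <- phangorn::rNNI(tr, config$nni_moves)
        tr
      },
      sequence_nj = {
        aln <- evolve_sequences(model_og, config$block_length, config$gtr)
        nj_tree(aln[c(kept, og), , drop = FALSE], og)
      })
  }
  union_leaves <- unique(unlist(lapply(inputs, leaf_labels)))
  list(model = model, model_outgroup = model_og, inputs = inputs,
       covered = setequal(union_leaves, model$tip.label) ||
         all(model$tip.label %in% union_leaves),
       config = config)
}

#' Number of unrooted binary tree topologies
#'
#' (2n - 5)!! unrooted binary topologies exist on n labeled leaves. The
#' magnitude is computed from the sum of log10 of the odd factors (stable
#' for any n); for n <= 500 the exact integer is also returned as a decimal
#' string.
#'
#' @param n Number of leaves (>= 3).
#' @return List with \code{mantissa} (one decimal), \code{exponent}
#'   (integer power of 10), and \code{exact} (decimal string for n <= 500,
#'   otherwise \code{NA}).
#' @examples
#' count_unrooted_trees(4)$exact        # "3"
#' count_unrooted_trees(10000)[1:2]     # 8.0 x 10^38658
#' @export
count_unrooted_trees <- function(n) {
  if (n < 3L) stop("'n' must be at least 3")
  factors <- if (n == 3L) 1 else seq(3, 2 * n - 5, by = 2)
  lg <- sum(log10(factors))
  expo <- floor(lg)
  mant <- round(10^(lg - expo), 1)
  if (mant >= 10) { mant <- mant / 10; expo <- expo + 1 }
  exact <- if (n <= 500L) bigprod_decimal(factors) else NA_character_
  list(mantissa = mant, exponent = as.integer(expo), exact = exact)
}

# exact product of small positive integers as a decimal string
# (base-1e4 limbs; factors up to 2n-5 keep limb products within double
# precision)
bigprod_decimal <- function(factors) {
  limbs <- 1  # little-endian base-10000 limbs
  for (f in factors) {
    limbs <- limbs * f
    carry <- 0
    for (i in seq_along(limbs)) {
      v <- limbs[i] + carry
      limbs[i] <- v %% 10000
      carry <- v %/% 10000
    }
    while (carry > 0) {
      limbs <- c(limbs, carry %% 10000)
      carry <- carry %/% 10000
    }
  }
  digits <- c(sprintf("%d", limbs[length(limbs)]),
              sprintf("%04d", rev(limbs[-length(limbs)])))
  paste(digits, collapse = "")
}
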