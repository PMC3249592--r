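#' Run the simulation benchmark
#'
#' For each replicate: generate a model tree and input trees
#' ([make_input_trees()]), run each requested supertree method, prune the
#' outgroup, and compare the supertree to the model tree
#' ([compare_trees()]). Build returning its incompatibility verdict is
#' recorded as a row with \code{status = "incompatible"}, not an error.
#'
#' @param config A [sim_config()]; its \code{seed} seeds replicate r with
#'   \code{seed + r - 1}.
#' @param methods Subset of \code{c("build", "mc", "mmc", "bwd_sac",
#'   "bwd_sacmax")}.
#' @param n_replicates Number of replicates.
#' @param mast Compute the MAST score per comparison (slowest metric)?
#' @param out Optional CSV path; rows are appended as they complete and
#'   finished replicates found in an existing file are not recomputed.
#' @param verbose Print one line per replicate?
#' @return A data frame of class \code{"benchmark_result"}: one row per
#'   (replicate, method) with the comparison metrics.
#' @export
run_benchmark <- function(config = sim_config(), methods = c("mc", "bwd_sac"),
                          n_replicates = 10L, mast = TRUE, out = NULL,
                          verbose = FALSE) {
  known <- c("build", "mc", "mmc", "bwd_sac", "bwd_sacmax")
  bad <- setdiff(methods, known)
  if (length(bad) > 0L)
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  done <- NULL
  if (!is.null(out) && file.exists(out)) {
    done <- utils::read.csv(out, stringsAsFactors = FALSE)
  }
  rows <- list()
  for (r in seq_len(n_replicates)) {
    rep_seed <- config$seed + r - 1L
    if (!is.null(done) && any(done$replicate == r & done$seed == rep_seed)) {
      rows[[length(rows) + 1L]] <- done[done$replicate == r, , drop = FALSE]
      next
    }
    cfg <- config
    cfg$seed <- rep_seed
    sim <- make_input_trees(cfg)
    rep_rows <- lapply(methods, function(m) {
      t0 <- proc.time()[["elapsed"]]
      st <- switch(m,
        build = build_supertree(sim$inputs),
        mc = mincut_supertree(sim$inputs),
        mmc = modified_mincut_supertree(sim$inputs),
        bwd_sac = bwd_supertree(sim$inputs, support = "sac"),
        bwd_sacmax = bwd_supertree(sim$inputs, support = "sacmax"))
      wall <- proc.time()[["elapsed"]] - t0
      base <- data.frame(replicate = r, method = m,
                         n_taxa = cfg$n_taxa,
                         deletion_ratio = cfg$deletion_ratio,
                         n_input_trees = cfg$n_input_trees,
                         input_mode = cfg$input_mode, seed = rep_seed,
                         stringsAsFactors = FALSE)
      if (is_incompatible(st)) {
        cbind(base, data.frame(
          status = "incompatible", resolution = NA_real_,
          rf_norm = NA_real_, d_tr = NA_real_, same = NA_integer_,
          diff = NA_integer_, r1 = NA_integer_, r2 = NA_integer_,
          x = NA_integer_, mast = NA_integer_, mast_norm = NA_real_,
          n_excluded = NA_integer_, covered = sim$covered,
          wall_time = wall))
      } else {
        cmp <- compare_trees(sim$model, st, mast = mast)
        cbind(base, data.frame(
          status = "ok", resolution = cmp$resolution,
          rf_norm = cmp$rf_norm, d_tr = cmp$d_tr,
          same = cmp$triplet$same, diff = cmp$triplet$diff,
          r1 = cmp$triplet$r1, r2 = cmp$triplet$r2, x = cmp$triplet$x,
          mast = cmp$mast, mast_norm = cmp$mast_norm,
          n_excluded = cmp$n_excluded_taxa, covered = sim$covered,
          wall_time = wall))
      }
    })
    rep_df <- do.call(rbind, rep_rows)
    rows[[length(rows) + 1L]] <- rep_df
    if (!is.null(out)) {
      utils::write.table(rep_df, out, sep = ",", row.names = FALSE,
                         col.names = !file.exists(out), append = file.exists(out))
    }
    if (verbose)
      message(sprintf("replicate %d/%d done", r, n_replicates))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("benchmark_result", class(res))
  res
}

#' Summarize benchmark results
#'
#' Mean and standard deviation of every metric per (method, n_input_trees,
#' deletion_ratio, n_taxa) group; groups without successful rows are
#' omitted.
#'
#' @param results A [run_benchmark()] result.
#' @return A data frame with one row per group.
#' @export
summarize_benchmark <- function(results) {
  if (nrow(results) == 0L) stop("'results' is empty")
  ok <- results[results$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) stop("no successful rows to summarize")
  metrics <- intersect(c("resolution", "rf_norm", "d_tr", "mast_norm"),
                       names(ok))
  grp <- interaction(ok$method, ok$n_input_trees, ok$deletion_ratio,
                     ok$n_taxa, drop = TRUE)
  parts <- lapply(split(seq_len(nrow(ok)), grp), function(ix) {
    sub <- ok[ix, , drop = FALSE]
    row <- data.frame(method = sub$method[1],
                      n_taxa = sub$n_taxa[1],
                      deletion_ratio = sub$deletion_ratio[1],
                      n_input_trees = sub$n_input_trees[1],
                      n = nrow(sub), stringsAsFactors = FALSE)
    for (m in metrics) {
      v <- sub[[m]]
      row[[paste0(m, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- stats::sd(v)
    }
    row
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$method, out$n_input_trees), , drop = FALSE]
}

#' Plot a benchmark summary
#'
#' Draws one metric against the number of input trees, one line per method
#' (base graphics).
#'
#' @param summary A [summarize_benchmark()] data frame.
#' @param metric Column stem to plot (e.g. \code{"resolution"},
#'   \code{"d_tr"}).
#' @return Invisibly, the summary.
#' @export
plot_benchmark <- function(summary, metric = "resolution") {
  col <- paste0(metric, "_mean")
  if (!col %in% names(summary)) stop("metric not found: ", metric)
  methods <- unique(summary$method)
  xs <- sort(unique(summary$n_input_trees))
  graphics::plot(NULL, xlim = range(xs), ylim = c(0, 1),
                 xlab = "input trees", ylab = metric)
  for (i in seq_along(methods)) {
    sub <- summary[summary$method == methods[i], , drop = FALSE]
    sub <- sub[order(sub$n_input_trees), ]
    graphics::lines(sub$n_input_trees, sub[[col]], col = i, type = "b")
  }
  graphics::legend("bottomright", legend = methods, col = seq_along(methods),
                   lty = 1, bty = "n")
  invisible(summary)
}
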