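# The single fitting entry point: runs every statistic of the analysis on
# one colony and returns a classed object with print/summary/plot methods.

#' Fit the full forced-proximity analysis to a colony
#'
#' Runs the whole inference suite on one colony: per-class mean changes in
#' allogrooming log rate with percentile-bootstrap CIs, the TEST-minus-
#' CONTROL difference with its constrained triad-reassignment permutation
#' p-value, the shift in the proportion of grooming directed to unfamiliar
#' partners, the familiar-vs-new trade-off correlation, the two rank linear
#' models with within-cage permutation p-values, and the Spearman
#' correlations between phase rates of the test dyads.
#'
#' @param colony a \code{\link{colony}}.
#' @param n_boot bootstrap resamples (default 5000).
#' @param n_perm Monte-Carlo permutations (default 5000).
#' @param level confidence level (default 0.95).
#' @param seed master seed; every resampling stage derives its own
#'   substream from it.
#' @param filter optional character vector of
#'   \code{\link{apply_robustness_filter}} names applied in order before
#'   fitting.
#' @param exhaustive_cap switch to exhaustive nulls at or below this many
#'   arrangements (default 100000).
#' @return An object of class \code{"proxbond_fit"}.
#' @examples
#' cfg <- sim_config(seed = 42)
#' col <- generate_colony(cfg)
#' fit <- analyze_colony(col, n_boot = 500, n_perm = 500, seed = 42)
#' fit
#' @export
analyze_colony <- function(colony, n_boot = 5000, n_perm = 5000,
                           level = 0.95, seed = 1, filter = NULL,
                           exhaustive_cap = 100000) {
  stopifnot(inherits(colony, "colony"))
  for (f in filter) colony <- apply_robustness_filter(colony, f)

  cls <- drop_excluded(classify_dyads(colony), colony$excluded_dyads)
  counts <- table(factor(cls$dyad_class,
                         levels = c("TEST", "CONTROL", "FAMILIAR")))
  changes <- dyad_changes(colony)
  group <- group_change_summary(changes, n_boot = n_boot, level = level,
                                seed = substream_seed(seed, 21L))
  permutation <- tryCatch(
    triad_permutation_test(colony, n_perm = n_perm,
                           seed = substream_seed(seed, 22L),
                           exhaustive_cap = exhaustive_cap),
    error = function(e) {
      warning("triad permutation test skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  proportion <- proportion_unfamiliar_shift(
    colony, n_boot = n_boot, level = level,
    seed = substream_seed(seed, 23L))
  tradeoff <- tradeoff_correlation(colony, n_boot = n_boot, level = level,
                                   seed = substream_seed(seed, 24L))
  rank_change <- rank_lm_change(colony, n_perm = n_perm,
                                seed = substream_seed(seed, 25L),
                                exhaustive_cap = exhaustive_cap)
  rank_post <- rank_lm_post(colony, n_perm = n_perm,
                            seed = substream_seed(seed, 26L),
                            exhaustive_cap = exhaustive_cap)
  phase_cor <- phase_correlations(colony)

  structure(list(
    colony = colony, dyad_counts = counts, changes = changes,
    group = group, permutation = permutation, proportion = proportion,
    tradeoff = tradeoff, rank_change = rank_change, rank_post = rank_post,
    phase_cor = phase_cor,
    settings = list(n_boot = n_boot, n_perm = n_perm, level = level,
                    seed = seed, filter = filter,
                    exhaustive_cap = exhaustive_cap)),
    class = "proxbond_fit")
}

#' @keywords internal
#' @noRd
fit_results_list <- function(x) {
  out <- c(x$group[c("test", "control", "familiar", "difference")],
           list(permutation = x$permutation, proportion = x$proportion,
                tradeoff = x$tradeoff, rank_change = x$rank_change,
                rank_post = x$rank_post),
           x$phase_cor)
  out[!vapply(out, is.null, logical(1))]
}

#' @export
as.data.frame.proxbond_fit <- function(x, ...) {
  df <- results_table(fit_results_list(x))
  df$seed <- x$settings$seed
  rownames(df) <- NULL
  df
}

#' @export
print.proxbond_fit <- function(x, digits = 3, ...) {
  cat("Forced-proximity analysis of dyadic allogrooming\n")
  cat(sprintf("Dyads: %d test, %d control, %d familiar\n",
              x$dyad_counts["TEST"], x$dyad_counts["CONTROL"],
              x$dyad_counts["FAMILIAR"]))
  if (!is.null(x$settings$filter)) {
    cat("Filters applied:", paste(x$settings$filter, collapse = ", "), "\n")
  }
  cat("\nMean change in allogrooming log rate (post - pre):\n")
  for (nm in c("test", "control", "familiar")) {
    r <- x$group[[nm]]
    if (is.null(r)) next
    cat(sprintf("  %-8s %6.3f log s/h  [%0.3f, %0.3f]\n", nm, r$estimate,
                r$ci_low, r$ci_high))
  }
  if (!is.null(x$permutation)) {
    cat(sprintf("  difference (test - control) = %0.3f, permutation p = %s\n",
                x$permutation$estimate,
                format(x$permutation$p_value, digits = digits)))
  }
  cat(sprintf("\nProportion of grooming to unfamiliar partners: shift = %0.3f [%0.3f, %0.3f]\n",
              x$proportion$estimate, x$proportion$ci_low,
              x$proportion$ci_high))
  cat(sprintf("Trade-off correlation (familiar vs new partners): r = %0.2f [%0.2f, %0.2f], p = %s\n",
              x$tradeoff$estimate, x$tradeoff$ci_low, x$tradeoff$ci_high,
              format(x$tradeoff$p_value, digits = digits)))
  fp <- x$phase_cor$forced_post
  fr <- x$phase_cor$forced_pre
  cat(sprintf("Spearman rho, forced vs post: %0.2f (p = %s); forced vs pre: %0.2f (p = %s)\n",
              fp$estimate, format(fp$p_value, digits = digits),
              fr$estimate, format(fr$p_value, digits = digits)))
  cat(sprintf("Rank model, change ~ forced: beta = %0.2f, p = %s, permutation p = %s\n",
              x$rank_change$estimate,
              format(x$rank_change$extra$parametric_p, digits = digits),
              format(x$rank_change$p_value, digits = digits)))
  cat(sprintf("Rank model, post ~ pre + forced: beta = %0.2f, p = %s, permutation p = %s\n",
              x$rank_post$estimate,
              format(x$rank_post$extra$parametric_p, digits = digits),
              format(x$rank_post$p_value, digits = digits)))
  invisible(x)
}

#' @export
summary.proxbond_fit <- function(object, ...) {
  structure(list(table = as.data.frame(object),
                 dyad_counts = object$dyad_counts,
                 settings = object$settings),
            class = "summary.proxbond_fit")
}

#' @export
print.summary.proxbond_fit <- function(x, digits = 3, ...) {
  cat("Forced-proximity analysis: statistic table\n")
  cat(sprintf("(%d test / %d control / %d familiar dyads; n_boot = %d, n_perm = %d, seed = %d)\n\n",
              x$dyad_counts["TEST"], x$dyad_counts["CONTROL"],
              x$dyad_counts["FAMILIAR"], x$settings$n_boot,
              x$settings$n_perm, x$settings$seed))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(col) {
    if (is.numeric(col)) signif(col, digits) else col
  })
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Dot-and-CI plot of per-class changes
#'
#' One panel: each dyad's change in allogrooming log rate as a jittered
#' point by class, with the class bootstrap mean and CI overlaid.
#'
#' @param x a \code{proxbond_fit}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.proxbond_fit <- function(x, ...) {
  classes <- c("FAMILIAR", "CONTROL", "TEST")
  ch <- x$changes
  at <- match(ch$dyad_class, classes)
  set.seed(1)
  graphics::plot(at + stats::runif(nrow(ch), -0.18, 0.18), ch$delta_log,
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.5),
                 xaxt = "n", xlab = "", xlim = c(0.5, 3.5),
                 ylab = "change in allogrooming log rate (post - pre)", ...)
  graphics::axis(1, at = 1:3, labels = tolower(classes))
  graphics::abline(h = 0, lty = 3)
  key <- c(FAMILIAR = "familiar", CONTROL = "control", TEST = "test")
  for (i in seq_along(classes)) {
    r <- x$group[[key[classes[i]]]]
    if (is.null(r)) next
    graphics::points(i, r$estimate, pch = 19, cex = 1.4)
    graphics::arrows(i, r$ci_low, i, r$ci_high, angle = 90, code = 3,
                     length = 0.06, lwd = 2)
  }
  invisible(x)
}
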