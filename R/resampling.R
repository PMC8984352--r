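# Resampling inference: percentile bootstrap CIs, the constrained
# triad-reassignment permutation test, per-bat partner-preference shifts,
# the familiar-vs-new trade-off correlation, rank linear models with
# within-cage permutation nulls, and phase-rate Spearman correlations.

#' Container for a resampled statistic
#'
#' @param statistic label of the statistic.
#' @param estimate point estimate.
#' @param ci_low,ci_high percentile CI bounds (or \code{NA}).
#' @param p_value p-value (or \code{NA}).
#' @param n_resamples number of resamples behind the CI / p-value.
#' @param resamples the stored vector of resampled statistics (bootstrap
#'   replicates or permutation null draws).
#' @param seed RNG seed used.
#' @param extra optional named list of auxiliary values (e.g. a parametric
#'   p-value alongside a permutation one).
#' @return An object of class \code{"resampling_result"}.
#' @export
resampling_result <- function(statistic, estimate, ci_low = NA_real_,
                              ci_high = NA_real_, p_value = NA_real_,
                              n_resamples = 0L, resamples = numeric(0),
                              seed = NA_integer_, extra = list()) {
  stopifnot(is.na(ci_low) || is.na(ci_high) || ci_low <= ci_high)
  structure(list(statistic = statistic, estimate = estimate,
                 ci_low = ci_low, ci_high = ci_high, p_value = p_value,
                 n_resamples = as.integer(n_resamples),
                 resamples = resamples, seed = seed, extra = extra),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, digits = 3, ...) {
  cat(x$statistic, ": ", format(x$estimate, digits = digits), sep = "")
  if (!is.na(x$ci_low)) {
    cat(sprintf(" [%s, %s]", format(x$ci_low, digits = digits),
                format(x$ci_high, digits = digits)))
  }
  if (!is.na(x$p_value)) cat(", p =", format(x$p_value, digits = digits))
  if (length(x$extra)) {
    cat(" (", paste(names(x$extra),
                    vapply(x$extra, format, "", digits = digits),
                    sep = " = ", collapse = ", "), ")", sep = "")
  }
  cat("  [", x$n_resamples, " resamples]\n", sep = "")
  invisible(x)
}

#' Percentile-bootstrap confidence interval for a mean
#'
#' Resamples \code{values} with replacement \code{n_boot} times and takes
#' empirical quantiles of the resampled means as CI bounds (percentile
#' method).
#'
#' @param values numeric vector (non-empty).
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param level confidence level in (0, 1) (default 0.95).
#' @param seed RNG seed.
#' @param statistic_name label for the result.
#' @return A \code{\link{resampling_result}} with the bootstrap replicates
#'   stored in \code{$resamples}.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 5000, level = 0.95, seed = 1,
                              statistic_name = "mean") {
  if (!length(values) || !is.numeric(values)) {
    stop("values must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  n <- length(values)
  set.seed(seed)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  means <- colMeans(matrix(values[idx], nrow = n, ncol = n_boot))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(means, c(alpha, 1 - alpha)))
  resampling_result(statistic_name, estimate = mean(values),
                    ci_low = ci[1], ci_high = ci[2],
                    n_resamples = n_boot, resamples = means, seed = seed)
}

#' Per-class mean changes with bootstrap CIs
#'
#' Bootstraps (resampling dyads) the mean change in allogrooming log rate
#' for each dyad class, and the TEST-minus-CONTROL difference (resampling
#' each class independently for its CI; the p-value for the difference
#' comes from \code{\link{triad_permutation_test}}).
#'
#' @param changes output of \code{\link{dyad_changes}}.
#' @param n_boot,level,seed as in \code{\link{bootstrap_mean_ci}}.
#' @return Named list of \code{\link{resampling_result}} objects:
#'   \code{test}, \code{control}, \code{familiar}, \code{difference}
#'   (classes absent from \code{changes} are skipped with a warning).
#' @export
group_change_summary <- function(changes, n_boot = 5000, level = 0.95,
                                 seed = 1) {
  out <- list()
  classes <- c(test = "TEST", control = "CONTROL", familiar = "FAMILIAR")
  for (i in seq_along(classes)) {
    v <- changes$delta_log[changes$dyad_class == classes[i]]
    if (!length(v)) {
      warning("no dyads in class ", classes[i], "; skipped", call. = FALSE)
      next
    }
    out[[names(classes)[i]]] <- bootstrap_mean_ci(
      v, n_boot = n_boot, level = level, seed = substream_seed(seed, i),
      statistic_name = paste0(tolower(classes[i]), "_mean_change"))
  }
  if (!is.null(out$test) && !is.null(out$control)) {
    diff_boot <- out$test$resamples - out$control$resamples
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(diff_boot, c(alpha, 1 - alpha)))
    out$difference <- resampling_result(
      "test_control_difference",
      estimate = out$test$estimate - out$control$estimate,
      ci_low = ci[1], ci_high = ci[2], n_resamples = n_boot,
      resamples = diff_boot, seed = seed)
  }
  out
}

#' @keywords internal
#' @noRd
bats_by_site <- function(x) {
  bats <- if (inherits(x, "colony")) x$bats else as.data.frame(x)
  split(bats$bat_id, bats$site)
}

#' Enumerate or count the site-complete triad assignments
#'
#' A triad assignment places the bats into unlabeled groups of one bat per
#' capture site. With \eqn{s} sites of \eqn{b} bats there are
#' \eqn{(b!)^{s-1}} distinct assignments (anchor one site, permute the
#' others). The full set is returned when it is no larger than
#' \code{max_count}; otherwise only the count.
#'
#' @param x a \code{\link{colony}} or a bats data.frame
#'   (\code{bat_id}, \code{site}).
#' @param max_count enumeration cap (default 100000).
#' @return List with \code{count} (double) and \code{assignments}: a list
#'   of named integer vectors (bat_id -> cage index), or \code{NULL} when
#'   the space exceeds \code{max_count}.
#' @export
enumerate_triad_assignments <- function(x, max_count = 100000) {
  by_site <- bats_by_site(x)
  sizes <- lengths(by_site)
  if (length(unique(sizes)) != 1) {
    stop("sites must have equal numbers of bats; got ",
         paste(sizes, collapse = ", "), call. = FALSE)
  }
  b <- sizes[[1]]
  s <- length(by_site)
  count <- factorial(b)^(s - 1)
  if (count > max_count) {
    return(list(count = count, assignments = NULL))
  }
  by_site <- lapply(by_site, sort)
  perms <- permutations(b)
  grids <- do.call(expand.grid, rep(list(seq_len(nrow(perms))), s - 1))
  assignments <- lapply(seq_len(nrow(grids)), function(i) {
    t_of <- stats::setNames(integer(b * s), unlist(by_site, use.names = FALSE))
    t_of[by_site[[1]]] <- seq_len(b)
    for (k in seq_len(s - 1)) {
      t_of[by_site[[k + 1]][perms[grids[i, k], ]]] <- seq_len(b)
    }
    t_of
  })
  list(count = count, assignments = assignments)
}

#' Draw uniform random site-complete triad assignments
#'
#' @param x a \code{\link{colony}} or bats data.frame.
#' @param n number of draws.
#' @param seed RNG seed (\code{NULL} to use the current RNG state).
#' @return List of \code{n} named integer vectors (bat_id -> cage index).
#' @export
sample_triad_assignments <- function(x, n, seed = NULL) {
  by_site <- bats_by_site(x)
  sizes <- lengths(by_site)
  if (length(unique(sizes)) != 1) {
    stop("sites must have equal numbers of bats; got ",
         paste(sizes, collapse = ", "), call. = FALSE)
  }
  b <- sizes[[1]]
  by_site <- lapply(by_site, sort)
  ids <- unlist(by_site, use.names = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    t_of <- stats::setNames(integer(length(ids)), ids)
    t_of[by_site[[1]]] <- seq_len(b)
    for (k in seq_along(by_site)[-1]) {
      t_of[sample(by_site[[k]])] <- seq_len(b)
    }
    t_of
  })
}

#' Constrained permutation test of the forced-proximity effect
#'
#' The statistic is the mean change in allogrooming log rate of TEST dyads
#' minus that of CONTROL dyads. The null distribution re-randomizes the
#' treatment: bats are re-assigned uniformly at random to new site-complete
#' triads, the cross-site dyads are relabeled TEST/CONTROL accordingly, and
#' the statistic is recomputed on the fixed per-dyad changes. Same-site
#' (FAMILIAR) dyads never enter the statistic. The exhaustive null is used
#' automatically when the assignment space is no larger than
#' \code{exhaustive_cap}; otherwise \code{n_perm} Monte-Carlo draws with
#' the add-one p-value \eqn{(1 + \#\{null \ge obs\})/(1 + n)}.
#'
#' @param colony a \code{\link{colony}}.
#' @param n_perm number of Monte-Carlo permutations (default 5000).
#' @param seed RNG seed.
#' @param alternative \code{"greater"} (default, directional hypothesis
#'   that forced proximity increases grooming), \code{"less"} or
#'   \code{"two.sided"}.
#' @param exhaustive_cap use exhaustive enumeration when the number of
#'   assignments is at most this (default 100000).
#' @return A \code{\link{resampling_result}}; \code{$extra$exhaustive}
#'   records which null was used.
#' @export
triad_permutation_test <- function(colony, n_perm = 5000, seed = 1,
                                   alternative = c("greater", "less",
                                                   "two.sided"),
                                   exhaustive_cap = 100000) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  ch <- dyad_changes(colony)
  smap <- site_map(colony)
  cross <- ch[smap[ch$bat_a] != smap[ch$bat_b], , drop = FALSE]
  if (!nrow(cross)) stop("no cross-site dyads with defined changes",
                         call. = FALSE)
  ids <- sort(colony$bats$bat_id)
  ai <- match(cross$bat_a, ids)
  bi <- match(cross$bat_b, ids)
  delta <- cross$delta_log
  S <- sum(delta)
  N <- length(delta)

  stat_for <- function(t_of) {
    test <- t_of[ai] == t_of[bi]
    n1 <- sum(test)
    if (n1 == 0 || n1 == N) return(NA_real_)
    s1 <- sum(delta[test])
    s1 / n1 - (S - s1) / (N - n1)
  }

  tmap <- triad_map(colony)
  t_obs <- stats::setNames(match(tmap[ids], unique(tmap[ids])), ids)
  observed <- stat_for(unname(t_obs))
  if (is.na(observed)) stop("observed assignment yields no TEST dyads",
                            call. = FALSE)

  space <- enumerate_triad_assignments(colony, max_count = exhaustive_cap)
  if (space$count < 2) {
    stop("design admits fewer than 2 distinct triad assignments",
         call. = FALSE)
  }
  if (!is.null(space$assignments)) {
    nulls <- vapply(space$assignments,
                    function(a) stat_for(unname(a[ids])), numeric(1))
    exhaustive <- TRUE
    p <- switch(alternative,
                greater = mean(nulls >= observed - 1e-12, na.rm = TRUE),
                less = mean(nulls <= observed + 1e-12, na.rm = TRUE),
                two.sided = mean(abs(nulls) >= abs(observed) - 1e-12,
                                 na.rm = TRUE))
  } else {
    draws <- sample_triad_assignments(colony, n_perm,
                                      seed = substream_seed(seed, 7L))
    nulls <- vapply(draws, function(a) stat_for(unname(a[ids])), numeric(1))
    exhaustive <- FALSE
    hits <- switch(alternative,
                   greater = sum(nulls >= observed - 1e-12, na.rm = TRUE),
                   less = sum(nulls <= observed + 1e-12, na.rm = TRUE),
                   two.sided = sum(abs(nulls) >= abs(observed) - 1e-12,
                                   na.rm = TRUE))
    p <- (1 + hits) / (1 + n_perm)
  }
  resampling_result("test_control_difference_perm", estimate = observed,
                    p_value = p, n_resamples = length(nulls),
                    resamples = nulls, seed = seed,
                    extra = list(exhaustive = exhaustive,
                                 alternative = alternative))
}

#' @keywords internal
#' @noRd
per_bat_sums <- function(rates, value, select = NULL) {
  ## sum `value` over the dyads each bat participates in
  sel <- if (is.null(select)) rep(TRUE, nrow(rates)) else select
  ids <- c(rates$bat_a, rates$bat_b)
  vals <- rep(value, 2)
  keep <- rep(sel, 2)
  out <- rowsum(vals[keep], group = ids[keep])
  stats::setNames(out[, 1], rownames(out))
}

#' Shift in the proportion of grooming directed to unfamiliar partners
#'
#' For each bat and phase, the proportion of its summed allogrooming log
#' rates that involves different-site (previously unfamiliar) partners.
#' The statistic is the mean over bats of the POST-minus-PRE change in
#' this proportion, with a percentile-bootstrap CI resampling bats. Bats
#' whose total rate is zero in either phase have an undefined proportion
#' and are dropped with a warning.
#'
#' @param colony a \code{\link{colony}}.
#' @param n_boot,level,seed as in \code{\link{bootstrap_mean_ci}}.
#' @param use_log sum log-transformed rates (default \code{TRUE}); set
#'   \code{FALSE} to sum raw seconds-per-hour rates instead.
#' @return A \code{\link{resampling_result}}; the per-bat changes are in
#'   \code{$extra$per_bat}.
#' @export
proportion_unfamiliar_shift <- function(colony, n_boot = 5000, level = 0.95,
                                        seed = 1, use_log = TRUE) {
  pr <- phase_rates(colony)
  val_col <- if (use_log) "rate_log" else "rate_s_per_h"
  prop_for <- function(phase) {
    sub <- pr[pr$phase == phase & !is.na(pr[[val_col]]), , drop = FALSE]
    tot <- per_bat_sums(sub, sub[[val_col]])
    dif <- per_bat_sums(sub, sub[[val_col]], sub$dyad_class != "FAMILIAR")
    dif <- dif[names(tot)]
    dif[is.na(dif)] <- 0
    out <- ifelse(tot > 0, dif / tot, NA_real_)
    stats::setNames(out, names(tot))
  }
  pre <- prop_for("PRE")
  post <- prop_for("POST")
  ids <- intersect(names(pre), names(post))
  change <- post[ids] - pre[ids]
  bad <- is.na(change)
  if (any(bad)) {
    warning("bat(s) with zero total rate in a phase dropped: ",
            paste(ids[bad], collapse = ", "), call. = FALSE)
    change <- change[!bad]
  }
  res <- bootstrap_mean_ci(unname(change), n_boot = n_boot, level = level,
                           seed = substream_seed(seed, 11L),
                           statistic_name = "proportion_unfamiliar_shift")
  res$seed <- seed
  res$extra <- list(per_bat = change)
  res
}

#' Trade-off between grooming familiar and new partners
#'
#' Pearson correlation, across bats, between each bat's mean change in
#' allogrooming log rate with familiar (same-site) partners and with
#' previously unfamiliar (different-site) partners; a clearly negative
#' correlation would indicate that new relationships come at the expense
#' of old ones. CI by percentile bootstrap resampling bats; two-sided
#' p-value from the standard correlation t-test.
#'
#' @param colony a \code{\link{colony}}.
#' @param n_boot,level,seed as in \code{\link{bootstrap_mean_ci}}.
#' @return A \code{\link{resampling_result}}.
#' @export
tradeoff_correlation <- function(colony, n_boot = 5000, level = 0.95,
                                 seed = 1) {
  ch <- dyad_changes(colony)
  fam_sum <- per_bat_sums(ch, ch$delta_log, ch$dyad_class == "FAMILIAR")
  fam_n <- per_bat_sums(ch, rep(1, nrow(ch)), ch$dyad_class == "FAMILIAR")
  new_sum <- per_bat_sums(ch, ch$delta_log, ch$dyad_class != "FAMILIAR")
  new_n <- per_bat_sums(ch, rep(1, nrow(ch)), ch$dyad_class != "FAMILIAR")
  ids <- intersect(names(fam_n)[fam_n > 0], names(new_n)[new_n > 0])
  if (length(ids) < 3) {
    stop("need at least 3 bats with both partner types", call. = FALSE)
  }
  fam <- fam_sum[ids] / fam_n[ids]
  new <- new_sum[ids] / new_n[ids]
  if (stats::sd(fam) == 0 || stats::sd(new) == 0) {
    stop("correlation undefined: constant per-bat changes", call. = FALSE)
  }
  r <- stats::cor(fam, new)
  p <- stats::cor.test(fam, new)$p.value
  set.seed(substream_seed(seed, 13L))
  n <- length(ids)
  boots <- vapply(seq_len(n_boot), function(i) {
    j <- sample.int(n, n, replace = TRUE)
    suppressWarnings(stats::cor(fam[j], new[j]))
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  resampling_result("tradeoff_correlation", estimate = r, ci_low = ci[1],
                    ci_high = ci[2], p_value = p, n_resamples = n_boot,
                    resamples = boots, seed = seed,
                    extra = list(n_bats = n))
}

#' Phase-level rate table for the test dyads
#'
#' One row per TEST dyad with its PRE, FORCED and POST allogrooming log
#' rates, the POST-minus-PRE change, and its forced-proximity cage.
#'
#' @param colony a \code{\link{colony}}.
#' @return data.frame with columns \code{bat_a}, \code{bat_b},
#'   \code{cage}, \code{pre_log}, \code{forced_log}, \code{post_log},
#'   \code{delta_log}.
#' @export
test_dyad_rates <- function(colony) {
  pr <- phase_rates(colony)
  pr <- pr[pr$dyad_class == "TEST", , drop = FALSE]
  wide <- stats::reshape(
    pr[, c("bat_a", "bat_b", "phase", "rate_log")],
    direction = "wide", idvar = c("bat_a", "bat_b"), timevar = "phase")
  names(wide) <- sub("^rate_log\\.", "", names(wide))
  tmap <- triad_map(colony)
  out <- data.frame(bat_a = wide$bat_a, bat_b = wide$bat_b,
                    cage = unname(tmap[wide$bat_a]),
                    pre_log = wide$PRE, forced_log = wide$FORCED,
                    post_log = wide$POST,
                    delta_log = wide$POST - wide$PRE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Generate within-cage permutations of seq_along(cage): either all
# arrangements (list of index vectors) or NULL if more than cap.
#' @keywords internal
#' @noRd
within_cage_arrangements <- function(cage, cap) {
  groups <- split(seq_along(cage), cage)
  total <- prod(factorial(lengths(groups)))
  if (total > cap) return(NULL)
  arr <- list(seq_along(cage))
  for (g in groups) {
    pm <- permutations(length(g))
    arr <- unlist(lapply(arr, function(base) {
      lapply(seq_len(nrow(pm)), function(i) {
        base[g] <- base[g][pm[i, ]]
        base
      })
    }), recursive = FALSE)
  }
  arr
}

#' @keywords internal
#' @noRd
shuffle_within_cages <- function(cage) {
  idx <- seq_along(cage)
  for (g in split(seq_along(cage), cage)) {
    if (length(g) > 1) idx[g] <- g[sample.int(length(g))]
  }
  idx
}

#' Rank model: does forced-proximity grooming predict the change?
#'
#' Ordinary least squares of the midranked POST-minus-PRE change in
#' allogrooming log rate of the TEST dyads on the midranked
#' forced-proximity log rate. Reports the slope, its two-sided parametric
#' p-value, and a one-sided (upper) permutation p-value obtained by
#' shuffling the forced-proximity rates among the dyads of each cage
#' independently, which preserves the cage structure under the null. The
#' exhaustive within-cage null is used when the number of arrangements is
#' at most \code{exhaustive_cap}.
#'
#' @param colony a \code{\link{colony}}.
#' @param n_perm number of Monte-Carlo permutations (default 5000).
#' @param seed RNG seed.
#' @param exhaustive_cap exhaustive-null cap (default 100000).
#' @return A \code{\link{resampling_result}} with the permutation p-value
#'   in \code{$p_value} and the parametric one in
#'   \code{$extra$parametric_p}.
#' @export
rank_lm_change <- function(colony, n_perm = 5000, seed = 1,
                           exhaustive_cap = 100000) {
  td <- test_dyad_rates(colony)
  rank_lm_perm(y = midrank(td$delta_log), x2 = midrank(td$forced_log),
               x1 = NULL, cage = td$cage, n_perm = n_perm, seed = seed,
               exhaustive_cap = exhaustive_cap,
               statistic = "rank_lm_change_beta")
}

#' Rank model: forced-proximity grooming vs post-treatment grooming
#'
#' As \code{\link{rank_lm_change}}, but the response is the midranked
#' post-treatment log rate and the midranked pre-treatment log rate enters
#' as a baseline covariate; the reported slope and permutation p-value
#' refer to the forced-proximity predictor (only the forced-phase rates
#' are shuffled within cages; the baseline stays fixed).
#'
#' @inheritParams rank_lm_change
#' @return A \code{\link{resampling_result}}.
#' @export
rank_lm_post <- function(colony, n_perm = 5000, seed = 1,
                         exhaustive_cap = 100000) {
  td <- test_dyad_rates(colony)
  rank_lm_perm(y = midrank(td$post_log), x2 = midrank(td$forced_log),
               x1 = midrank(td$pre_log), cage = td$cage, n_perm = n_perm,
               seed = seed, exhaustive_cap = exhaustive_cap,
               statistic = "rank_lm_post_beta")
}

#' @keywords internal
#' @noRd
rank_lm_perm <- function(y, x2, x1, cage, n_perm, seed, exhaustive_cap,
                         statistic) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (length(unique(x2)) < 2) {
    stop("degenerate fit: fewer than 2 distinct predictor ranks",
         call. = FALSE)
  }
  n <- length(y)
  cy <- y - mean(y)
  cx2 <- x2 - mean(x2)
  beta_for <- if (is.null(x1)) {
    Sxx <- sum(cx2^2)
    function(x2p) sum((x2p - mean(x2p)) * cy) / Sxx
  } else {
    cx1 <- x1 - mean(x1)
    S11 <- sum(cx1^2)
    S1y <- sum(cx1 * cy)
    S22 <- sum(cx2^2)  # invariant under within-cage shuffles of x2
    function(x2p) {
      c2 <- x2p - mean(x2p)
      S12 <- sum(cx1 * c2)
      S2y <- sum(c2 * cy)
      (S11 * S2y - S12 * S1y) / (S11 * S22 - S12^2)
    }
  }
  beta_obs <- beta_for(x2)

  ## parametric two-sided p from the OLS t-test
  fit <- if (is.null(x1)) stats::lm(y ~ x2) else stats::lm(y ~ x1 + x2)
  parametric_p <- stats::coef(summary(fit))["x2", "Pr(>|t|)"]

  arr <- within_cage_arrangements(cage, exhaustive_cap)
  if (!is.null(arr)) {
    nulls <- vapply(arr, function(idx) beta_for(x2[idx]), numeric(1))
    p <- mean(nulls >= beta_obs - 1e-12)
    exhaustive <- TRUE
  } else {
    set.seed(substream_seed(seed, 17L))
    nulls <- vapply(seq_len(n_perm), function(i) {
      beta_for(x2[shuffle_within_cages(cage)])
    }, numeric(1))
    p <- (1 + sum(nulls >= beta_obs - 1e-12)) / (1 + n_perm)
    exhaustive <- FALSE
  }
  resampling_result(statistic, estimate = beta_obs, p_value = p,
                    n_resamples = length(nulls), resamples = nulls,
                    seed = seed,
                    extra = list(parametric_p = parametric_p,
                                 exhaustive = exhaustive))
}

#' Spearman correlations between phase rates of the test dyads
#'
#' Rank correlations of the forced-proximity allogrooming log rate with
#' the post-treatment rate and with the pre-treatment rate, with two-sided
#' p-values (large-sample approximation, midranks for ties).
#'
#' @param colony a \code{\link{colony}}.
#' @return Named list of two \code{\link{resampling_result}} objects:
#'   \code{forced_post} and \code{forced_pre}.
#' @export
phase_correlations <- function(colony) {
  td <- test_dyad_rates(colony)
  one <- function(a, b, name) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stop("correlation undefined: constant phase rates", call. = FALSE)
    }
    ct <- stats::cor.test(a, b, method = "spearman", exact = FALSE)
    resampling_result(name, estimate = unname(ct$estimate),
                      p_value = ct$p.value, n_resamples = 0L,
                      extra = list(n_dyads = length(a)))
  }
  list(forced_post = one(td$forced_log, td$post_log,
                         "spearman_forced_post"),
       forced_pre = one(td$forced_log, td$pre_log,
                        "spearman_forced_pre"))
}
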