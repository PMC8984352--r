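test_that("bootstrap of a constant vector collapses to a point", {
  r <- bootstrap_mean_ci(rep(2.5, 8), n_boot = 200, seed = 1)
  expect_equal(r$estimate, 2.5)
  expect_equal(r$ci_low, 2.5)
  expect_equal(r$ci_high, 2.5)
})

test_that("bootstrap CIs are deterministic in the seed and reject bad input", {
  v <- c(0.3, 1.2, -0.5, 2.2, 0.8)
  r1 <- bootstrap_mean_ci(v, n_boot = 500, seed = 42)
  r2 <- bootstrap_mean_ci(v, n_boot = 500, seed = 42)
  expect_identical(c(r1$ci_low, r1$ci_high), c(r2$ci_low, r2$ci_high))
  r3 <- bootstrap_mean_ci(v, n_boot = 500, seed = 43)
  expect_false(identical(r1$ci_low, r3$ci_low))
  expect_error(bootstrap_mean_ci(numeric(0)), "non-empty")
  expect_error(bootstrap_mean_ci(v, level = 1.2), "level")
})

test_that("group summaries reduce correctly on degenerate change sets", {
  zero <- data.frame(dyad_class = rep(c("TEST", "CONTROL", "FAMILIAR"), 3),
                     delta_log = 0)
  g <- group_change_summary(zero, n_boot = 100, seed = 1)
  expect_equal(g$test$estimate, 0)
  expect_equal(g$difference$estimate, 0)
  expect_equal(g$difference$ci_low, 0)

  two <- data.frame(dyad_class = c("TEST", "TEST", "CONTROL", "CONTROL"),
                    delta_log = c(1, 1, 0, 0))
  expect_warning(g2 <- group_change_summary(two, n_boot = 100, seed = 1),
                 "FAMILIAR")
  expect_equal(g2$difference$estimate, 1)
})

test_that("triad assignment spaces have the exact enumerable sizes", {
  ## 3 sites x 2 bats: (2!)^2 = 4 distinct assignments
  e32 <- enumerate_triad_assignments(
    toy_colony(NULL, n_sites = 3, bats_per_site = 2))
  expect_equal(e32$count, 4)
  expect_length(e32$assignments, 4)
  ## all distinct, all site-complete partitions
  keys <- vapply(e32$assignments, function(a) {
    paste(sort(paste(names(a), a)), collapse = ";")
  }, character(1))
  expect_equal(length(unique(keys)), 4)
  for (a in e32$assignments) {
    expect_equal(sort(unique(a)), 1:2)
    expect_true(all(table(a) == 3))
  }
  ## 2 sites x 2 bats: 2 assignments
  expect_equal(enumerate_triad_assignments(toy_colony(NULL))$count, 2)
  ## study design: (7!)^2, count only
  e37 <- enumerate_triad_assignments(generate_colony(sim_config(seed = 1)))
  expect_equal(e37$count, factorial(7)^2)
  expect_equal(e37$count, 25401600)
  expect_null(e37$assignments)
  ## unequal site sizes are a design error
  bats <- data.frame(bat_id = c("x1", "x2", "y1"),
                     site = c("s1", "s1", "s2"))
  expect_error(enumerate_triad_assignments(bats), "equal numbers")
})

test_that("random triad assignments are valid partitions", {
  col <- toy_colony(NULL, n_sites = 3, bats_per_site = 2)
  draws <- sample_triad_assignments(col, 50, seed = 4)
  smap <- setNames(col$bats$site, col$bats$bat_id)
  for (a in draws) {
    expect_true(all(table(a) == 3))
    for (cage in split(names(a), a)) {
      expect_equal(sort(unname(smap[cage])), sort(unique(col$bats$site)))
    }
  }
})

test_that("exchangeable changes give a degenerate permutation p of 1", {
  ## no bouts at all: every dyad's change is 0, every null equals observed
  col <- toy_colony(NULL, n_sites = 3, bats_per_site = 2)
  r <- triad_permutation_test(col, n_perm = 50, seed = 1)
  expect_equal(r$estimate, 0)
  expect_equal(r$p_value, 1)
  expect_true(all(r$resamples == 0))
})

test_that("the observed statistic equals the direct group difference", {
  col <- generate_colony(small_sim(seed = 9))
  ch <- dyad_changes(col)
  direct <- mean(ch$delta_log[ch$dyad_class == "TEST"]) -
    mean(ch$delta_log[ch$dyad_class == "CONTROL"])
  r <- triad_permutation_test(col, n_perm = 20, seed = 2)
  expect_equal(r$estimate, direct, tolerance = 1e-12)
  ## p bounded below by 1/(n+1) and above by 1
  expect_gte(r$p_value, 1 / (r$n_resamples + 1))
  expect_lte(r$p_value, 1)
})

test_that("Monte-Carlo permutation p converges to the exhaustive p", {
  col <- generate_colony(small_sim(seed = 14))
  ex <- triad_permutation_test(col, seed = 1, exhaustive_cap = 10)
  expect_true(ex$extra$exhaustive)
  expect_equal(ex$n_resamples, 4)
  n_mc <- 4000
  mc <- triad_permutation_test(col, n_perm = n_mc, seed = 5,
                               exhaustive_cap = 1)
  expect_false(mc$extra$exhaustive)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / n_mc)
  expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 2 / n_mc)
})

test_that("the permutation test sees dyads, not bat id strings", {
  col <- generate_colony(small_sim(seed = 25))
  renamed <- col
  swap <- function(v) paste0("zz_", v)
  renamed$bats$bat_id <- swap(renamed$bats$bat_id)
  renamed$triads$bat_id <- swap(renamed$triads$bat_id)
  renamed$bouts$actor <- swap(renamed$bouts$actor)
  renamed$bouts$receiver <- swap(renamed$bouts$receiver)
  r1 <- triad_permutation_test(col, n_perm = 200, seed = 3)
  r2 <- triad_permutation_test(renamed, n_perm = 200, seed = 3)
  expect_equal(r2$estimate, r1$estimate, tolerance = 1e-12)
  expect_equal(r2$p_value, r1$p_value)
})

test_that("grooming aimed solely at familiar partners shows no proportion shift", {
  col <- toy_colony(rbind(bout_row(1, "a1", "a2", 40),
                          bout_row(1, "b1", "b2", 80),
                          bout_row(6, "a2", "a1", 20),
                          bout_row(7, "b2", "b1", 60)))
  r <- proportion_unfamiliar_shift(col, n_boot = 100, seed = 1)
  expect_equal(r$estimate, 0)
  expect_true(all(r$extra$per_bat == 0))
})

test_that("identical PRE and POST rate tables give a zero proportion shift", {
  col <- toy_colony(rbind(bout_row(1, "a1", "b1", 30),
                          bout_row(2, "a1", "a2", 50),
                          bout_row(5, "a1", "b1", 30),
                          bout_row(6, "a1", "a2", 50)),
                    pre_hours = c(4, 4), forced_hours = c(4, 4),
                    post_hours = c(4, 4))
  expect_warning(r <- proportion_unfamiliar_shift(col, n_boot = 100,
                                                  seed = 1),
                 "zero total")
  expect_equal(r$estimate, 0)
  expect_true(r$ci_low <= 0 && 0 <= r$ci_high)
})

test_that("a forced-proximity boost shifts grooming toward unfamiliar partners", {
  col <- generate_colony(small_sim(seed = 40, treatment_effect_delta = 1.5))
  r <- proportion_unfamiliar_shift(col, n_boot = 300, seed = 2)
  expect_gt(r$estimate, 0)
})

test_that("matched familiar and unfamiliar changes give a trade-off r of 1", {
  ## POST-only bouts engineered so each bat's mean change to familiar
  ## partners equals its mean change to different-site partners:
  ## per-bat targets g = (1, 2, 3) per site; cross dyad (i, j) gets
  ## g_i + g_j - 2, familiar dyads solve the within-site system.
  H <- 16  # POST exposure hours in the default toy design
  dur <- function(delta) 2 * H * expm1(delta)
  rows <- list()
  g <- c(1, 2, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      d <- g[i] + g[j] - 2
      if (d > 0) {
        rows[[length(rows) + 1]] <-
          bout_row(6, paste0("a", i), paste0("b", j), dur(d))
      }
    }
  }
  fam <- list(c(1, 3, 2), c(2, 3, 4))  # pairs (1,3)->2 and (2,3)->4; (1,2)->0
  for (s in c("a", "b")) {
    for (f in fam) {
      rows[[length(rows) + 1]] <-
        bout_row(6, paste0(s, f[1]), paste0(s, f[2]), dur(f[3]))
    }
  }
  col <- toy_colony(do.call(rbind, rows), n_sites = 2, bats_per_site = 3)
  r <- tradeoff_correlation(col, n_boot = 100, seed = 1)
  expect_equal(r$estimate, 1, tolerance = 1e-8)
})

test_that("trade-off correlation is undefined for constant changes", {
  expect_error(tradeoff_correlation(toy_colony(NULL), n_boot = 50, seed = 1),
               "constant|at least 3")
})

test_that("rank model recovers a slope of 1 for identically ordered ranks", {
  ## FORCED durations order the 6 test dyads; POST durations follow the
  ## same order, PRE is empty, so both rank vectors coincide
  rows <- list()
  pairs <- list(c("a1", "b1"), c("b1", "c1"), c("a1", "c1"),
                c("a2", "b2"), c("b2", "c2"), c("a2", "c2"))
  for (k in seq_along(pairs)) {
    rows[[length(rows) + 1]] <- bout_row(4, pairs[[k]][1], pairs[[k]][2],
                                         20 * k)
    rows[[length(rows) + 1]] <- bout_row(6, pairs[[k]][1], pairs[[k]][2],
                                         35 * k)
  }
  col <- toy_colony(do.call(rbind, rows), n_sites = 3, bats_per_site = 2)
  r <- rank_lm_change(col, n_perm = 100, seed = 1)
  expect_equal(r$estimate, 1, tolerance = 1e-12)
  expect_true(r$extra$exhaustive)  # 2 cages -> 36 arrangements
  expect_equal(r$n_resamples, 36)
  expect_gte(r$p_value, 1 / 36)

  ## post identical to forced with a distinct pre ordering: the forced
  ## coefficient in the two-predictor model is exactly 1
  pre_rows <- lapply(seq_along(pairs), function(k) {
    bout_row(1, pairs[[k]][1], pairs[[k]][2], 15 * ((k * 3) %% 7 + 1))
  })
  col2 <- toy_colony(do.call(rbind, c(rows, pre_rows)),
                     n_sites = 3, bats_per_site = 2)
  td <- test_dyad_rates(col2)
  expect_false(all(rank(td$pre_log) == rank(td$forced_log)))
  r2 <- rank_lm_post(col2, n_perm = 100, seed = 1)
  expect_equal(r2$estimate, 1, tolerance = 1e-8)
})

test_that("rank-model permutation p is deterministic and MC matches exhaustive", {
  col <- generate_colony(small_sim(seed = 18))
  a <- rank_lm_change(col, n_perm = 300, seed = 7, exhaustive_cap = 1)
  b <- rank_lm_change(col, n_perm = 300, seed = 7, exhaustive_cap = 1)
  expect_identical(a$p_value, b$p_value)
  ex <- rank_lm_change(col, seed = 1)  # 2 cages: exhaustive 36
  expect_true(ex$extra$exhaustive)
  n_mc <- 4000
  mc <- rank_lm_change(col, n_perm = n_mc, seed = 2, exhaustive_cap = 1)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / n_mc)
  expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 2 / n_mc)
})

test_that("degenerate rank predictors raise an error", {
  rows <- rbind(bout_row(4, "a1", "b1", 50), bout_row(4, "b1", "c1", 50),
                bout_row(4, "a1", "c1", 50), bout_row(4, "a2", "b2", 50),
                bout_row(4, "b2", "c2", 50), bout_row(4, "a2", "c2", 50))
  col <- toy_colony(rows, n_sites = 3, bats_per_site = 2)
  expect_error(rank_lm_change(col, n_perm = 10, seed = 1), "degenerate")
})

test_that("phase correlations hit the rank-correlation extremes", {
  rows <- list()
  pairs <- list(c("a1", "b1"), c("b1", "c1"), c("a1", "c1"),
                c("a2", "b2"), c("b2", "c2"), c("a2", "c2"))
  for (k in seq_along(pairs)) {
    rows[[length(rows) + 1]] <- bout_row(4, pairs[[k]][1], pairs[[k]][2],
                                         20 * k)
    ## POST durations reversed relative to FORCED
    rows[[length(rows) + 1]] <- bout_row(6, pairs[[k]][1], pairs[[k]][2],
                                         20 * (7 - k))
    ## PRE follows the FORCED order
    rows[[length(rows) + 1]] <- bout_row(1, pairs[[k]][1], pairs[[k]][2],
                                         10 * k)
  }
  col <- toy_colony(do.call(rbind, rows), n_sites = 3, bats_per_site = 2)
  pc <- phase_correlations(col)
  expect_equal(pc$forced_post$estimate, -1, tolerance = 1e-12)
  expect_equal(pc$forced_pre$estimate, 1, tolerance = 1e-12)
  expect_error(phase_correlations(toy_colony(NULL)), "constant")
})
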