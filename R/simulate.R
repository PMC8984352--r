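# Synthetic colony generator. Bout counts are Poisson per session and
# ordered pair, with a log-linear rate: a baseline for unfamiliar pairs, a
# familiarity multiplier for same-site pairs, a log-normal dyad random
# effect shared by both directions of a pair, and an additive log-scale
# treatment shift for dyads forced into proximity. Durations are 5 s plus
# an exponential tail.

#' Configuration of the synthetic colony generator
#'
#' Defaults emulate the study design: 21 bats, 3 capture sites of 7, a
#' 6-week pre-treatment phase, 1 week of forced proximity in 7 site-complete
#' triads, a 9-week post-treatment phase, and 3-6 h of observation per day.
#'
#' @param n_sites number of capture sites (default 3).
#' @param bats_per_site bats per site (default 7; must be >= 2 so familiar
#'   dyads exist).
#' @param phase_lengths_days lengths in days of the PRE, FORCED and POST
#'   phases (default \code{c(42, 7, 63)}).
#' @param hours_range integer range of observation hours per day, drawn
#'   uniformly (default \code{c(3, 6)}).
#' @param base_rate_lambda expected directed bouts per co-observable hour
#'   for an unfamiliar pair (default 0.15). Zero is allowed and yields a
#'   boutless colony.
#' @param familiarity_multiplier rate multiplier for same-site pairs
#'   (default 3).
#' @param treatment_effect_delta additive shift, on the log-rate scale,
#'   applied to test dyads while the treatment is active (default 0.5;
#'   0 gives the null model).
#' @param treatment_in_forced logical; apply the shift during the FORCED
#'   phase as well as POST (default \code{TRUE}).
#' @param dyad_sd standard deviation of the dyad-level Normal log-rate
#'   effect, shared by both directions of a pair (default 0.6).
#' @param bout_mean_s mean of the exponential part of the bout duration
#'   above the 5 s floor (default 95, i.e. mean bout 100 s).
#' @param seed master RNG seed; all substreams derive from it.
#' @param start_date first observation day (ISO-8601 string or Date).
#'
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_sites = 3, bats_per_site = 7,
                       phase_lengths_days = c(42, 7, 63),
                       hours_range = c(3, 6),
                       base_rate_lambda = 0.15,
                       familiarity_multiplier = 3,
                       treatment_effect_delta = 0.5,
                       treatment_in_forced = TRUE,
                       dyad_sd = 0.6,
                       bout_mean_s = 95,
                       seed = 1,
                       start_date = "2019-06-23") {
  cfg <- list(n_sites = as.integer(n_sites),
              bats_per_site = as.integer(bats_per_site),
              phase_lengths_days = as.integer(phase_lengths_days),
              hours_range = as.integer(hours_range),
              base_rate_lambda = as.numeric(base_rate_lambda),
              familiarity_multiplier = as.numeric(familiarity_multiplier),
              treatment_effect_delta = as.numeric(treatment_effect_delta),
              treatment_in_forced = isTRUE(treatment_in_forced),
              dyad_sd = as.numeric(dyad_sd),
              bout_mean_s = as.numeric(bout_mean_s),
              seed = as.integer(seed),
              start_date = as.Date(start_date))
  bad <- function(field, why) {
    stop(sprintf("invalid sim_config: %s %s", field, why), call. = FALSE)
  }
  if (cfg$n_sites < 2) bad("n_sites", "must be >= 2")
  if (cfg$bats_per_site < 2) bad("bats_per_site", "must be >= 2")
  if (length(cfg$phase_lengths_days) != 3 || any(cfg$phase_lengths_days < 1)) {
    bad("phase_lengths_days", "must be three positive day counts")
  }
  if (length(cfg$hours_range) != 2 || cfg$hours_range[1] < 1 ||
      cfg$hours_range[2] < cfg$hours_range[1]) {
    bad("hours_range", "must be an increasing positive integer range")
  }
  if (is.na(cfg$base_rate_lambda) || cfg$base_rate_lambda < 0) {
    bad("base_rate_lambda", "must be >= 0")
  }
  if (cfg$familiarity_multiplier <= 0) {
    bad("familiarity_multiplier", "must be > 0")
  }
  if (cfg$treatment_effect_delta < 0) {
    bad("treatment_effect_delta", "must be >= 0")
  }
  if (cfg$dyad_sd < 0) bad("dyad_sd", "must be >= 0")
  if (cfg$bout_mean_s <= 0) bad("bout_mean_s", "must be > 0")
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  structure(cfg, class = "sim_config")
}

#' @keywords internal
#' @noRd
update_sim_config <- function(cfg, ...) {
  upd <- list(...)
  cfg <- unclass(cfg)
  cfg[names(upd)] <- upd
  do.call(sim_config, cfg)
}

#' Generate one synthetic colony
#'
#' Draws a colony under the generative model described in
#' \code{\link{sim_config}}: triads uniformly at random subject to
#' one-bat-per-site; per session and ordered co-observable pair, bout count
#' \eqn{\sim} Poisson(hours \eqn{\times \lambda}) with
#' \deqn{\log\lambda = \log\lambda_0 + [\mathrm{same\ site}]\log m +
#'   u_{pair} + [\mathrm{test,\ treated\ phase}]\,\delta,}
#' \eqn{u_{pair} \sim N(0, \sigma^2)} shared by both directions; durations
#' \eqn{5 + \mathrm{Exp}(\mu)}. The same config and seed always reproduce
#' the identical colony.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A validated \code{\link{colony}}.
#' @export
generate_colony <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_bats <- config$n_sites * config$bats_per_site
  width <- max(2L, nchar(as.character(n_bats)))
  sites <- paste0("site", LETTERS[seq_len(config$n_sites)])
  bats <- data.frame(
    bat_id = sprintf(paste0("bat%0", width, "d"), seq_len(n_bats)),
    site = rep(sites, each = config$bats_per_site),
    excluded_low_sampling = FALSE, excluded_infection = FALSE,
    stringsAsFactors = FALSE)

  ## triads: anchor the first site's bats in order, permute the others
  set.seed(substream_seed(config$seed, 1L))
  members <- matrix("", nrow = config$bats_per_site, ncol = config$n_sites)
  for (k in seq_len(config$n_sites)) {
    ids <- bats$bat_id[bats$site == sites[k]]
    members[, k] <- if (k == 1L) ids else sample(ids)
  }
  triads <- data.frame(
    triad_id = rep(sprintf("cage%d", seq_len(config$bats_per_site)),
                   times = config$n_sites),
    bat_id = as.vector(members), stringsAsFactors = FALSE)

  ## phases and sessions
  len <- config$phase_lengths_days
  starts <- config$start_date + c(0L, cumsum(len)[-3])
  phases <- data.frame(phase = PHASES, start_date = starts,
                       end_date = starts + len - 1L,
                       stringsAsFactors = FALSE)
  dates <- seq(config$start_date, by = "day", length.out = sum(len))
  set.seed(substream_seed(config$seed, 2L))
  sessions <- data.frame(
    date = dates,
    phase = rep(PHASES, times = len),
    hours_sampled = as.numeric(
      seq(config$hours_range[1], config$hours_range[2])[sample.int(
        config$hours_range[2] - config$hours_range[1] + 1L,
        sum(len), replace = TRUE)]),
    stringsAsFactors = FALSE)

  ## dyad-level structure (canonical pair order)
  pairs <- all_pairs(bats$bat_id)
  smap <- site_map(colony = list(bats = bats))
  tmap <- stats::setNames(triads$triad_id, triads$bat_id)
  same_site <- smap[pairs$bat_a] == smap[pairs$bat_b]
  same_triad <- tmap[pairs$bat_a] == tmap[pairs$bat_b]
  set.seed(substream_seed(config$seed, 3L))
  u <- stats::rnorm(nrow(pairs), 0, config$dyad_sd)
  log_lam0 <- if (config$base_rate_lambda > 0) {
    log(config$base_rate_lambda) + same_site * log(config$familiarity_multiplier) + u
  } else rep(-Inf, nrow(pairs))

  lam_phase <- function(phase) {
    treated <- same_triad & !same_site &
      ((phase == "POST") || (phase == "FORCED" && config$treatment_in_forced))
    exp(log_lam0 + ifelse(treated, config$treatment_effect_delta, 0))
  }

  ## Poisson counts per (session, ordered pair), phase by phase
  set.seed(substream_seed(config$seed, 4L))
  blocks <- list()
  for (phase in PHASES) {
    co <- if (phase == "FORCED") which(same_triad) else seq_len(nrow(pairs))
    if (!length(co)) next
    sidx <- which(sessions$phase == phase)
    lam <- lam_phase(phase)[co]
    mu <- as.vector(outer(lam, sessions$hours_sampled[sidx]))  # pairs vary fastest
    n_ab <- stats::rpois(length(mu), mu)
    n_ba <- stats::rpois(length(mu), mu)
    tot <- sum(n_ab) + sum(n_ba)
    if (tot == 0) next
    pr <- rep(co, times = length(sidx))
    sr <- rep(sidx, each = length(co))
    blocks[[phase]] <- data.frame(
      date = sessions$date[c(rep(sr, n_ab), rep(sr, n_ba))],
      actor = c(rep(pairs$bat_a[pr], n_ab), rep(pairs$bat_b[pr], n_ba)),
      receiver = c(rep(pairs$bat_b[pr], n_ab), rep(pairs$bat_a[pr], n_ba)),
      stringsAsFactors = FALSE)
  }
  bouts <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(date = as.Date(character()), actor = character(),
               receiver = character(), stringsAsFactors = FALSE)
  rownames(bouts) <- NULL

  set.seed(substream_seed(config$seed, 5L))
  bouts$duration_s <- if (nrow(bouts)) {
    5 + stats::rexp(nrow(bouts), rate = 1 / config$bout_mean_s)
  } else numeric(0)
  bouts <- bouts[order(bouts$date), , drop = FALSE]
  rownames(bouts) <- NULL

  colony(bats = bats, phases = phases, triads = triads, sessions = sessions,
         bouts = bouts)
}

#' Generate an ensemble of null colonies
#'
#' Draws \code{n_datasets} independent colonies with the treatment effect
#' forced to zero, for calibration studies of the resampling tests. Child
#' seeds are derived deterministically from \code{config$seed}, so the
#' ensemble is reproducible and its members are distinct.
#'
#' @param config a \code{\link{sim_config}}; its
#'   \code{treatment_effect_delta} is overridden with 0.
#' @param n_datasets number of colonies (>= 1).
#' @return A list of \code{\link{colony}} objects.
#' @export
generate_null_ensemble <- function(config, n_datasets) {
  stopifnot(inherits(config, "sim_config"))
  n_datasets <- as.integer(n_datasets)
  if (is.na(n_datasets) || n_datasets < 1) {
    stop("n_datasets must be >= 1", call. = FALSE)
  }
  lapply(seq_len(n_datasets), function(i) {
    generate_colony(update_sim_config(
      config, treatment_effect_delta = 0,
      seed = substream_seed(config$seed, 1000L + i)))
  })
}
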