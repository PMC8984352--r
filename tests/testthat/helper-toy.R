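# Hand-buildable miniature colonies for oracle tests.

# Bats are named <site letter><index> (a1, a2, b1, ...); cage j holds the
# j-th bat of every site. Phase lengths are given by the hours vectors.
toy_design <- function(n_sites = 2, bats_per_site = 2,
                       pre_hours = c(4, 5, 3), forced_hours = c(4, 4),
                       post_hours = c(6, 6, 4),
                       start = as.Date("2020-01-01")) {
  sites <- paste0("site", LETTERS[seq_len(n_sites)])
  bats <- data.frame(
    bat_id = paste0(rep(letters[seq_len(n_sites)], each = bats_per_site),
                    rep(seq_len(bats_per_site), n_sites)),
    site = rep(sites, each = bats_per_site),
    excluded_low_sampling = FALSE, excluded_infection = FALSE,
    stringsAsFactors = FALSE)
  triads <- data.frame(
    triad_id = paste0("cage", rep(seq_len(bats_per_site), n_sites)),
    bat_id = bats$bat_id, stringsAsFactors = FALSE)
  lens <- c(length(pre_hours), length(forced_hours), length(post_hours))
  dates <- seq(start, by = "day", length.out = sum(lens))
  sessions <- data.frame(
    date = dates, phase = rep(c("PRE", "FORCED", "POST"), times = lens),
    hours_sampled = c(pre_hours, forced_hours, post_hours),
    stringsAsFactors = FALSE)
  starts <- start + c(0L, cumsum(lens)[-3])
  phases <- data.frame(phase = c("PRE", "FORCED", "POST"),
                       start_date = starts,
                       end_date = starts + lens - 1L,
                       stringsAsFactors = FALSE)
  list(bats = bats, triads = triads, sessions = sessions, phases = phases,
       start = start)
}

# bouts: data.frame(day = 1-based session index, actor, receiver, duration_s)
toy_colony <- function(bouts = NULL, ..., validate = TRUE) {
  d <- toy_design(...)
  bt <- if (is.null(bouts) || !nrow(bouts)) {
    data.frame(date = as.Date(character()), actor = character(),
               receiver = character(), duration_s = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(date = d$start + bouts$day - 1L, actor = bouts$actor,
               receiver = bouts$receiver, duration_s = bouts$duration_s,
               stringsAsFactors = FALSE)
  }
  colony(bats = d$bats, phases = d$phases, triads = d$triads,
         sessions = d$sessions, bouts = bt, validate = validate)
}

bout_row <- function(day, actor, receiver, duration_s) {
  data.frame(day = day, actor = actor, receiver = receiver,
             duration_s = duration_s, stringsAsFactors = FALSE)
}

# Small, fast simulation settings for property tests.
small_sim <- function(...) {
  args <- list(n_sites = 3, bats_per_site = 2,
               phase_lengths_days = c(6, 3, 6), base_rate_lambda = 0.5,
               bout_mean_s = 25)
  upd <- list(...)
  args[names(upd)] <- upd
  do.call(sim_config, args)
}

rate_for <- function(rates, a, b, phase) {
  rates$rate_log[rates$bat_a == a & rates$bat_b == b & rates$phase == phase]
}
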