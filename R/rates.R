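# Dyadic allogrooming rates. The rate of a pair in a phase is the mean of
# its two directed seconds-per-hour rates over all exposure hours (hours in
# which both bats could interact), transformed with ln(1 + x). During the
# forced-proximity phase only cage-mates have exposure; a dyad with zero
# exposure has an undefined (NA) rate, never a numeric 0.

#' Classify every dyad by familiarity and treatment
#'
#' Pairs from the same capture site are \code{FAMILIAR}; different-site
#' pairs that share a forced-proximity cage are \code{TEST}; the remaining
#' different-site pairs are \code{CONTROL}. The three classes partition all
#' \eqn{\binom{n}{2}} pairs. Under the study design (3 sites of 7 bats,
#' 7 triads) this yields 21 TEST, 126 CONTROL and 63 FAMILIAR dyads.
#'
#' @param colony a \code{\link{colony}}.
#' @return data.frame with columns \code{bat_a}, \code{bat_b}
#'   (canonically ordered) and \code{dyad_class}.
#' @export
classify_dyads <- function(colony) {
  stopifnot(inherits(colony, "colony"))
  smap <- site_map(colony)
  tmap <- triad_map(colony)
  if (any(!colony$bats$bat_id %in% names(tmap))) {
    stop("bat(s) missing a triad assignment: ",
         paste(setdiff(colony$bats$bat_id, names(tmap)), collapse = ", "),
         call. = FALSE)
  }
  pairs <- all_pairs(colony$bats$bat_id)
  same_site <- smap[pairs$bat_a] == smap[pairs$bat_b]
  same_triad <- tmap[pairs$bat_a] == tmap[pairs$bat_b]
  pairs$dyad_class <- ifelse(same_site, "FAMILIAR",
                             ifelse(same_triad, "TEST", "CONTROL"))
  rownames(pairs) <- NULL
  pairs
}

#' Exposure hours of a dyad in a phase
#'
#' Total sampled hours during which the two bats could interact: in PRE and
#' POST every pair shares the flight cage, during FORCED only cage-mates
#' have exposure.
#'
#' @param colony a \code{\link{colony}}.
#' @param bat_a,bat_b bat ids (order irrelevant).
#' @param phase one of \code{"PRE"}, \code{"FORCED"}, \code{"POST"}.
#' @return Nonnegative hours.
#' @export
exposure_hours <- function(colony, bat_a, bat_b, phase) {
  stopifnot(inherits(colony, "colony"))
  if (!phase %in% PHASES) stop("unknown phase: ", phase, call. = FALSE)
  ids <- colony$bats$bat_id
  if (!all(c(bat_a, bat_b) %in% ids)) {
    stop("unknown bat id(s): ",
         paste(setdiff(c(bat_a, bat_b), ids), collapse = ", "), call. = FALSE)
  }
  hours <- sum(colony$sessions$hours_sampled[colony$sessions$phase == phase])
  if (phase == "FORCED") {
    tmap <- triad_map(colony)
    if (tmap[bat_a] != tmap[bat_b]) return(0)
  }
  hours
}

#' Phase-level log rates for all dyads
#'
#' Computes, for every non-excluded dyad and every phase, the exposure
#' hours, the symmetric seconds-per-hour rate \eqn{x} (total grooming
#' seconds in both directions divided by twice the exposure, i.e. the mean
#' of the two directed rates) and the allogrooming log rate
#' \eqn{\ln(1 + x)}. Dyads with zero exposure in a phase get \code{NA}.
#'
#' @param colony a \code{\link{colony}}.
#' @return data.frame with columns \code{bat_a}, \code{bat_b},
#'   \code{dyad_class}, \code{phase}, \code{exposure_h},
#'   \code{rate_s_per_h}, \code{rate_log}.
#' @export
phase_rates <- function(colony) {
  stopifnot(inherits(colony, "colony"))
  cls <- classify_dyads(colony)
  cls <- drop_excluded(cls, colony$excluded_dyads)
  tmap <- triad_map(colony)
  phase_hours <- vapply(PHASES, function(p) {
    sum(colony$sessions$hours_sampled[colony$sessions$phase == p])
  }, numeric(1))

  grid <- cls[rep(seq_len(nrow(cls)), times = 3), ]
  grid$phase <- rep(PHASES, each = nrow(cls))
  grid$exposure_h <- phase_hours[grid$phase]
  forced <- grid$phase == "FORCED"
  grid$exposure_h[forced & tmap[grid$bat_a] != tmap[grid$bat_b]] <- 0

  grid$key <- paste(pair_key(grid$bat_a, grid$bat_b), grid$phase)
  secs <- stats::setNames(rep(0, nrow(grid)), grid$key)
  bo <- colony$bouts
  if (nrow(bo)) {
    bphase <- colony$sessions$phase[match(bo$date, colony$sessions$date)]
    bkey <- paste(pair_key(bo$actor, bo$receiver), bphase)
    tot <- rowsum(bo$duration_s, group = bkey)
    hit <- rownames(tot) %in% grid$key
    secs[rownames(tot)[hit]] <- tot[hit, 1]
  }
  grid$rate_s_per_h <- ifelse(grid$exposure_h > 0,
                              secs / (2 * grid$exposure_h), NA_real_)
  grid$rate_log <- log1p(grid$rate_s_per_h)
  grid$key <- NULL
  rownames(grid) <- NULL
  grid
}

#' @keywords internal
#' @noRd
drop_excluded <- function(pairs, excluded) {
  if (is.null(excluded) || !nrow(excluded)) return(pairs)
  bad <- pair_key(pairs$bat_a, pairs$bat_b) %in%
    pair_key(excluded$bat_a, excluded$bat_b)
  pairs[!bad, , drop = FALSE]
}

#' Allogrooming log rate of one dyad in one phase
#'
#' @inheritParams exposure_hours
#' @return A one-row data.frame with \code{bat_a}, \code{bat_b},
#'   \code{phase}, \code{exposure_h}, \code{rate_s_per_h} and
#'   \code{rate_log}; the rates are \code{NA} when the dyad has no exposure
#'   in the phase.
#' @export
dyad_log_rate <- function(colony, bat_a, bat_b, phase) {
  h <- exposure_hours(colony, bat_a, bat_b, phase)
  p <- canonical_pair(bat_a, bat_b)
  secs <- 0
  bo <- colony$bouts
  if (nrow(bo)) {
    bphase <- colony$sessions$phase[match(bo$date, colony$sessions$date)]
    sel <- bphase == phase &
      ((bo$actor == p$a & bo$receiver == p$b) |
         (bo$actor == p$b & bo$receiver == p$a))
    secs <- sum(bo$duration_s[sel])
  }
  x <- if (h > 0) secs / (2 * h) else NA_real_
  data.frame(bat_a = p$a, bat_b = p$b, phase = phase, exposure_h = h,
             rate_s_per_h = x, rate_log = log1p(x),
             stringsAsFactors = FALSE)
}

#' Per-dyad change in allogrooming log rate
#'
#' The change score \eqn{\Delta} = POST log rate minus PRE log rate, with
#' dyad class attached. Dyads lacking exposure in either phase are dropped
#' with a warning.
#'
#' @param colony a \code{\link{colony}}.
#' @return data.frame with columns \code{bat_a}, \code{bat_b},
#'   \code{dyad_class}, \code{pre_log}, \code{post_log}, \code{delta_log}.
#' @export
dyad_changes <- function(colony) {
  pr <- phase_rates(colony)
  pre <- pr[pr$phase == "PRE", ]
  post <- pr[pr$phase == "POST", ]
  out <- data.frame(bat_a = pre$bat_a, bat_b = pre$bat_b,
                    dyad_class = pre$dyad_class,
                    pre_log = pre$rate_log,
                    post_log = post$rate_log,
                    stringsAsFactors = FALSE)
  out$delta_log <- out$post_log - out$pre_log
  miss <- is.na(out$delta_log)
  if (any(miss)) {
    warning(sum(miss), " dyad(s) without exposure in PRE or POST dropped",
            call. = FALSE)
    out <- out[!miss, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Windowed log-rate time series per dyad
#'
#' Splits each phase into consecutive windows of \code{window_days} days
#' (the last window of a phase may be shorter) and computes the
#' allogrooming log rate per dyad and window, for time-course reporting of
#' whether an effect persists throughout the post-treatment phase. Windows
#' in which a dyad has no exposure give \code{NA}.
#'
#' @param colony a \code{\link{colony}}.
#' @param window_days window length in days (>= 1).
#' @return data.frame with columns \code{bat_a}, \code{bat_b},
#'   \code{dyad_class}, \code{phase}, \code{window}, \code{window_start},
#'   \code{exposure_h}, \code{rate_log}.
#' @export
windowed_rates <- function(colony, window_days) {
  stopifnot(inherits(colony, "colony"))
  window_days <- as.integer(window_days)
  if (is.na(window_days) || window_days < 1) {
    stop("window_days must be >= 1", call. = FALSE)
  }
  cls <- drop_excluded(classify_dyads(colony), colony$excluded_dyads)
  tmap <- triad_map(colony)
  se <- colony$sessions
  ph <- colony$phases[match(se$phase, colony$phases$phase), ]
  win <- as.integer(se$date - ph$start_date) %/% window_days + 1L
  wkey <- paste(se$phase, win)
  whours <- rowsum(se$hours_sampled, group = wkey)
  wtab <- unique(data.frame(phase = se$phase, window = win,
                            window_start = ph$start_date +
                              (win - 1L) * window_days,
                            key = wkey, stringsAsFactors = FALSE))
  wtab <- wtab[order(match(wtab$phase, PHASES), wtab$window), ]

  grid <- cls[rep(seq_len(nrow(cls)), times = nrow(wtab)), ]
  grid$phase <- rep(wtab$phase, each = nrow(cls))
  grid$window <- rep(wtab$window, each = nrow(cls))
  grid$window_start <- rep(wtab$window_start, each = nrow(cls))
  grid$exposure_h <- whours[rep(wtab$key, each = nrow(cls)), 1]
  forced <- grid$phase == "FORCED"
  grid$exposure_h[forced & tmap[grid$bat_a] != tmap[grid$bat_b]] <- 0

  grid$gkey <- paste(pair_key(grid$bat_a, grid$bat_b), grid$phase, grid$window)
  secs <- stats::setNames(rep(0, nrow(grid)), grid$gkey)
  bo <- colony$bouts
  if (nrow(bo)) {
    i <- match(bo$date, se$date)
    bkey <- paste(pair_key(bo$actor, bo$receiver), se$phase[i], win[i])
    tot <- rowsum(bo$duration_s, group = bkey)
    hit <- rownames(tot) %in% grid$gkey
    secs[rownames(tot)[hit]] <- tot[hit, 1]
  }
  grid$rate_log <- ifelse(grid$exposure_h > 0,
                          log1p(secs / (2 * grid$exposure_h)), NA_real_)
  grid$gkey <- NULL
  rownames(grid) <- NULL
  grid
}

#' Robustness filters on a colony
#'
#' Reproduces the study's sensitivity analyses:
#' \describe{
#'   \item{\code{high_pre_controls}}{excludes CONTROL dyads whose
#'     pre-treatment log rate exceeds the maximum pre-treatment log rate
#'     observed among TEST dyads (guards against regression to the mean);
#'     the excluded pairs are recorded on the colony and honoured by all
#'     downstream statistics.}
#'   \item{\code{low_sampling_bats}}{drops bats flagged
#'     \code{excluded_low_sampling}, together with their bouts, triad rows
#'     and all their dyads.}
#'   \item{\code{infected_bats}}{likewise for \code{excluded_infection}.}
#' }
#'
#' @param colony a \code{\link{colony}}.
#' @param which filter name.
#' @return The filtered \code{\link{colony}}.
#' @export
apply_robustness_filter <- function(colony,
                                    which = c("high_pre_controls",
                                              "low_sampling_bats",
                                              "infected_bats")) {
  stopifnot(inherits(colony, "colony"))
  which <- match.arg(which)
  if (which == "high_pre_controls") {
    pr <- phase_rates(colony)
    pre <- pr[pr$phase == "PRE", ]
    max_test <- suppressWarnings(
      max(pre$rate_log[pre$dyad_class == "TEST"], na.rm = TRUE))
    drop <- !is.na(pre$rate_log) & pre$dyad_class == "CONTROL" &
      pre$rate_log > max_test
    colony$excluded_dyads <- unique(rbind(
      colony$excluded_dyads,
      pre[drop, c("bat_a", "bat_b"), drop = FALSE]))
    rownames(colony$excluded_dyads) <- NULL
    return(colony)
  }
  flag <- if (which == "low_sampling_bats") "excluded_low_sampling" else
    "excluded_infection"
  gone <- colony$bats$bat_id[colony$bats[[flag]]]
  if (!length(gone)) return(colony)
  keep_bat <- !colony$bats$bat_id %in% gone
  bo <- colony$bouts
  keep_bout <- !(bo$actor %in% gone | bo$receiver %in% gone)
  colony(bats = colony$bats[keep_bat, , drop = FALSE],
         phases = colony$phases,
         triads = colony$triads[!colony$triads$bat_id %in% gone, ,
                                drop = FALSE],
         sessions = colony$sessions,
         bouts = bo[keep_bout, , drop = FALSE],
         excluded_dyads = colony$excluded_dyads,
         allow_incomplete_triads = TRUE)
}
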