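#' Assemble and validate a colony dataset
#'
#' A colony bundles everything one run of the analysis needs: the individuals
#' with their capture sites and exclusion flags, the three experimental phases
#' (free association, forced proximity, free association again), the
#' forced-proximity triad membership, the daily observation sessions, and the
#' directed allogrooming bouts.
#'
#' @param bats data.frame with columns \code{bat_id}, \code{site},
#'   \code{excluded_low_sampling}, \code{excluded_infection}.
#' @param phases data.frame with columns \code{phase} (\code{"PRE"},
#'   \code{"FORCED"}, \code{"POST"}), \code{start_date}, \code{end_date}
#'   (Date or ISO-8601 strings). Phases must be contiguous, non-overlapping
#'   and ordered PRE < FORCED < POST.
#' @param triads data.frame in long format with columns \code{triad_id},
#'   \code{bat_id}; each triad holds one bat per capture site and the triads
#'   partition the colony.
#' @param sessions data.frame with columns \code{date}, \code{phase},
#'   \code{hours_sampled}.
#' @param bouts data.frame with columns \code{date}, \code{actor},
#'   \code{receiver}, \code{duration_s}; one row per directed grooming bout.
#' @param excluded_dyads optional data.frame with columns \code{bat_a},
#'   \code{bat_b}: pairs removed from all downstream statistics (used by
#'   \code{\link{apply_robustness_filter}}).
#' @param validate validate the assembled object (default \code{TRUE}).
#' @param ... passed on to \code{\link{validate_colony}}.
#'
#' @return An object of class \code{"colony"}: a list with the five
#'   components above plus \code{excluded_dyads}.
#' @seealso \code{\link{read_colony}}, \code{\link{generate_colony}}
#' @export
colony <- function(bats, phases, triads, sessions, bouts,
                   excluded_dyads = NULL, validate = TRUE, ...) {
  bats <- as.data.frame(bats, stringsAsFactors = FALSE)
  phases <- as.data.frame(phases, stringsAsFactors = FALSE)
  triads <- as.data.frame(triads, stringsAsFactors = FALSE)
  sessions <- as.data.frame(sessions, stringsAsFactors = FALSE)
  bouts <- as.data.frame(bouts, stringsAsFactors = FALSE)

  phases$start_date <- as.Date(phases$start_date)
  phases$end_date <- as.Date(phases$end_date)
  sessions$date <- as.Date(sessions$date)
  sessions$hours_sampled <- as.numeric(sessions$hours_sampled)
  if (nrow(bouts)) bouts$date <- as.Date(bouts$date)
  for (col in c("excluded_low_sampling", "excluded_infection")) {
    bats[[col]] <- as.logical(bats[[col]])
  }
  bats$bat_id <- as.character(bats$bat_id)
  bats$site <- as.character(bats$site)
  triads$triad_id <- as.character(triads$triad_id)
  triads$bat_id <- as.character(triads$bat_id)
  if (nrow(bouts)) {
    bouts$actor <- as.character(bouts$actor)
    bouts$receiver <- as.character(bouts$receiver)
    bouts$duration_s <- as.numeric(bouts$duration_s)
  }
  if (is.null(excluded_dyads)) {
    excluded_dyads <- data.frame(bat_a = character(), bat_b = character(),
                                 stringsAsFactors = FALSE)
  }

  obj <- structure(
    list(bats = bats, phases = phases, triads = triads,
         sessions = sessions, bouts = bouts,
         excluded_dyads = as.data.frame(excluded_dyads)),
    class = "colony")
  if (validate) validate_colony(obj, ...)
  obj
}

#' Validate the invariants of a colony
#'
#' Checks referential integrity and the design invariants: unique bat ids,
#' site-complete triads that partition the colony, contiguous ordered phases,
#' session dates inside their phase, sampling hours within bounds, bout
#' durations at or above the minimum, actors distinct from receivers, and
#' (during the forced-proximity phase) bouts only between cage-mates.
#'
#' @param x a \code{\link{colony}}.
#' @param strict logical; if \code{FALSE}, violations that real-world data
#'   plausibly contain (cross-cage bouts during forced proximity, hours out
#'   of bounds) downgrade from errors to warnings and offending bouts are
#'   dropped.
#' @param min_bout_s minimum bout duration that should already have been
#'   enforced at ingest (default 5 seconds).
#' @param hours_bounds length-2 numeric: allowed range of
#'   \code{hours_sampled} per session (default \code{c(3, 6)}).
#' @param allow_incomplete_triads logical; permit triads with fewer members
#'   than sites (set after bat-level robustness filters).
#'
#' @return \code{x}, invisibly (possibly with bouts dropped under
#'   \code{strict = FALSE}).
#' @export
validate_colony <- function(x, strict = TRUE, min_bout_s = 5,
                            hours_bounds = c(3, 6),
                            allow_incomplete_triads = FALSE) {
  stopifnot(inherits(x, "colony"))
  fail <- function(...) stop(sprintf(...), call. = FALSE)

  if (anyDuplicated(x$bats$bat_id)) fail("duplicated bat_id in bats table")
  sites <- unique(x$bats$site)

  ## phases: PRE < FORCED < POST, contiguous, non-overlapping
  ph <- x$phases
  if (!identical(sort(ph$phase), sort(PHASES))) {
    fail("phases must be exactly PRE, FORCED, POST")
  }
  ph <- ph[match(PHASES, ph$phase), ]
  if (any(ph$end_date < ph$start_date)) fail("phase end_date before start_date")
  if (any(diff(as.numeric(ph$start_date)) <= 0)) {
    fail("phases must be ordered PRE < FORCED < POST")
  }
  gaps <- as.numeric(ph$start_date[-1]) - as.numeric(ph$end_date[-3])
  if (any(gaps != 1)) fail("phases must be contiguous and non-overlapping")

  ## triads: members exist, partition, one per site (unless filtered)
  tr <- x$triads
  if (any(!tr$bat_id %in% x$bats$bat_id)) {
    fail("triad member(s) not in bats table: %s",
         paste(setdiff(tr$bat_id, x$bats$bat_id), collapse = ", "))
  }
  if (anyDuplicated(tr$bat_id)) fail("bat assigned to more than one triad")
  if (any(!x$bats$bat_id %in% tr$bat_id)) {
    fail("bat(s) missing a triad assignment: %s",
         paste(setdiff(x$bats$bat_id, tr$bat_id), collapse = ", "))
  }
  site_of <- x$bats$site[match(tr$bat_id, x$bats$bat_id)]
  dup_site <- tapply(site_of, tr$triad_id, anyDuplicated)
  if (any(dup_site > 0)) {
    fail("triad(s) with two members from the same site: %s",
         paste(names(dup_site)[dup_site > 0], collapse = ", "))
  }
  if (!allow_incomplete_triads) {
    n_mem <- table(tr$triad_id)
    if (any(n_mem != length(sites))) {
      fail("triad(s) not site-complete: %s",
           paste(names(n_mem)[n_mem != length(sites)], collapse = ", "))
    }
  }

  ## sessions: date within its phase, hours within bounds
  se <- x$sessions
  if (!all(se$phase %in% PHASES)) fail("session with unknown phase label")
  pidx <- match(se$phase, ph$phase)
  bad_date <- se$date < ph$start_date[pidx] | se$date > ph$end_date[pidx]
  if (any(bad_date)) {
    fail("session date(s) outside their phase: %s",
         paste(format(se$date[bad_date]), collapse = ", "))
  }
  bad_hours <- se$hours_sampled < hours_bounds[1] |
    se$hours_sampled > hours_bounds[2] | se$hours_sampled <= 0
  if (any(bad_hours)) {
    msg <- sprintf("%d session(s) with hours_sampled outside [%g, %g]",
                   sum(bad_hours), hours_bounds[1], hours_bounds[2])
    if (strict) fail(msg) else warning(msg, call. = FALSE)
  }

  ## bouts
  bo <- x$bouts
  if (nrow(bo)) {
    unknown <- !(bo$actor %in% x$bats$bat_id) |
      !(bo$receiver %in% x$bats$bat_id)
    if (any(unknown)) {
      fail("bout rows with unknown bat_id: rows %s",
           paste(utils::head(which(unknown), 10), collapse = ", "))
    }
    if (any(bo$actor == bo$receiver)) {
      fail("bout rows with actor == receiver: rows %s",
           paste(utils::head(which(bo$actor == bo$receiver), 10),
                 collapse = ", "))
    }
    if (any(bo$duration_s < min_bout_s)) {
      fail("bout rows below the %g s minimum duration: rows %s", min_bout_s,
           paste(utils::head(which(bo$duration_s < min_bout_s), 10),
                 collapse = ", "))
    }
    if (any(!bo$date %in% se$date)) {
      fail("bout date(s) with no observation session: %s",
           paste(utils::head(format(unique(bo$date[!bo$date %in% se$date])), 5),
                 collapse = ", "))
    }
    ## co-observability during forced proximity: cage-mates only
    forced_dates <- se$date[se$phase == "FORCED"]
    in_forced <- bo$date %in% forced_dates
    if (any(in_forced)) {
      triad_of <- tr$triad_id[match(x$bats$bat_id, tr$bat_id)]
      names(triad_of) <- x$bats$bat_id
      cross <- in_forced &
        triad_of[bo$actor] != triad_of[bo$receiver]
      if (any(cross)) {
        msg <- sprintf(
          "%d bout(s) between bats in different cages during FORCED: rows %s",
          sum(cross), paste(utils::head(which(cross), 10), collapse = ", "))
        if (strict) fail(msg)
        warning(paste(msg, "- dropped"), call. = FALSE)
        x$bouts <- bo[!cross, , drop = FALSE]
      }
    }
  }
  invisible(x)
}

#' @export
print.colony <- function(x, ...) {
  cat("Colony:", nrow(x$bats), "bats from",
      length(unique(x$bats$site)), "sites,",
      length(unique(x$triads$triad_id)), "forced-proximity cages\n")
  cat("Sessions:", nrow(x$sessions), "days,",
      round(sum(x$sessions$hours_sampled), 1), "h sampled",
      sprintf("(PRE %d / FORCED %d / POST %d days)\n",
              sum(x$sessions$phase == "PRE"),
              sum(x$sessions$phase == "FORCED"),
              sum(x$sessions$phase == "POST")))
  cat("Bouts:", nrow(x$bouts), "directed allogrooming bouts\n")
  if (nrow(x$excluded_dyads)) {
    cat("Excluded dyads:", nrow(x$excluded_dyads), "\n")
  }
  invisible(x)
}

# Named vector bat_id -> site
#' @keywords internal
#' @noRd
site_map <- function(colony) {
  stats::setNames(colony$bats$site, colony$bats$bat_id)
}

# Named vector bat_id -> triad_id
#' @keywords internal
#' @noRd
triad_map <- function(colony) {
  stats::setNames(colony$triads$triad_id, colony$triads$bat_id)
}
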