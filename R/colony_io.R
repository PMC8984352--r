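# CSV readers/writers. Dialect: comma-separated, UTF-8, mandatory header,
# ISO-8601 dates; numerics written with 17 significant digits so that a
# write/read round trip is bit-exact.

#' Read a colony from its CSV file set
#'
#' Expects four files in \code{dir} (or explicit paths): \code{bats.csv}
#' (\code{bat_id,site,excluded_low_sampling,excluded_infection}),
#' \code{sessions.csv} (\code{date,phase,hours_sampled}), \code{triads.csv}
#' (\code{triad_id,bat_id}, long format) and \code{bouts.csv}
#' (\code{date,actor,receiver,duration_s}). Bouts shorter than
#' \code{min_bout_s} are dropped at ingest with a message; everything else
#' is validated via \code{\link{validate_colony}}.
#'
#' @param dir directory containing the four CSV files.
#' @param paths optional named character vector/list overriding individual
#'   file locations (names among \code{bats}, \code{sessions}, \code{triads},
#'   \code{bouts}).
#' @param min_bout_s ingest filter: minimum bout duration in seconds
#'   (default 5).
#' @param strict strict validation (default \code{TRUE}); see
#'   \code{\link{validate_colony}}.
#' @param quiet suppress the dropped-bout message.
#' @return A validated \code{\link{colony}}.
#' @export
read_colony <- function(dir = NULL, paths = NULL, min_bout_s = 5,
                        strict = TRUE, quiet = FALSE) {
  files <- c(bats = "bats.csv", sessions = "sessions.csv",
             triads = "triads.csv", bouts = "bouts.csv")
  loc <- if (!is.null(dir)) file.path(dir, files) else character(4)
  names(loc) <- names(files)
  if (!is.null(paths)) loc[names(paths)] <- unlist(paths)
  missing <- !file.exists(loc)
  if (any(missing)) {
    stop("input file(s) not found: ", paste(loc[missing], collapse = ", "),
         call. = FALSE)
  }
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8")
  bats <- rd(loc["bats"])
  sessions <- rd(loc["sessions"])
  triads <- rd(loc["triads"])
  bouts <- rd(loc["bouts"])

  need <- list(
    bats = c("bat_id", "site", "excluded_low_sampling", "excluded_infection"),
    sessions = c("date", "phase", "hours_sampled"),
    triads = c("triad_id", "bat_id"),
    bouts = c("date", "actor", "receiver", "duration_s"))
  tabs <- list(bats = bats, sessions = sessions, triads = triads,
               bouts = bouts)
  for (nm in names(need)) {
    absent <- setdiff(need[[nm]], names(tabs[[nm]]))
    if (length(absent)) {
      stop(sprintf("%s is missing column(s): %s", basename(loc[nm]),
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
  }

  n_total <- nrow(bouts)
  keep <- bouts$duration_s >= min_bout_s
  if (!quiet && any(!keep)) {
    message(sprintf("read_colony: dropped %d of %d bouts shorter than %g s",
                    sum(!keep), n_total, min_bout_s))
  }
  bouts <- bouts[keep, , drop = FALSE]

  ## phase intervals are implied by the sessions table
  sessions$date <- as.Date(sessions$date)
  phases <- do.call(rbind, lapply(PHASES, function(p) {
    d <- sessions$date[sessions$phase == p]
    if (!length(d)) stop("no sessions in phase ", p, call. = FALSE)
    data.frame(phase = p, start_date = min(d), end_date = max(d),
               stringsAsFactors = FALSE)
  }))
  ## make contiguous: each phase ends the day before the next begins
  phases$end_date[1:2] <- phases$start_date[2:3] - 1

  colony(bats = bats, phases = phases, triads = triads, sessions = sessions,
         bouts = bouts, validate = TRUE, strict = strict,
         min_bout_s = min_bout_s)
}

#' @keywords internal
#' @noRd
fmt_num <- function(x) {
  ## 17 significant digits: lossless round trip for doubles
  ifelse(is.na(x), "", sub("0*e", "e", formatC(x, digits = 17, format = "g")))
}

#' @keywords internal
#' @noRd
write_csv_exact <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (col in names(df)[num]) df[[col]] <- fmt_num(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write a colony to its CSV file set
#'
#' Inverse of \code{\link{read_colony}}: writes \code{bats.csv},
#' \code{sessions.csv}, \code{triads.csv} and \code{bouts.csv} into
#' \code{dir}. Numeric columns keep full double precision, so
#' \code{read_colony(write_colony(x))} reproduces \code{x} exactly.
#'
#' @param colony a \code{\link{colony}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_colony <- function(colony, dir) {
  stopifnot(inherits(colony, "colony"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_exact(colony$bats, file.path(dir, "bats.csv"))
  se <- colony$sessions
  se$date <- format(se$date)
  write_csv_exact(se, file.path(dir, "sessions.csv"))
  write_csv_exact(colony$triads, file.path(dir, "triads.csv"))
  bo <- colony$bouts
  if (nrow(bo)) bo$date <- format(bo$date)
  write_csv_exact(bo, file.path(dir, "bouts.csv"))
  invisible(dir)
}

#' Write resampling results to a flat CSV
#'
#' Serialises a collection of \code{\link{resampling_result}} objects (or a
#' whole \code{\link{analyze_colony}} fit) to one row per statistic with
#' columns \code{statistic,estimate,ci_low,ci_high,p_value,n_resamples,seed}.
#' Output is bit-stable for a fixed seed and input.
#'
#' @param results a list of \code{resampling_result} objects, a single one,
#'   or a \code{proxbond_fit}.
#' @param path output file path.
#' @return The results table, invisibly.
#' @export
write_results <- function(results, path) {
  df <- results_table(results)
  if (is.null(df) || !nrow(df)) stop("no results to write", call. = FALSE)
  write_csv_exact(df, path)
  invisible(df)
}

#' @keywords internal
#' @noRd
results_table <- function(results) {
  if (inherits(results, "proxbond_fit")) return(as.data.frame(results))
  if (inherits(results, "resampling_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(statistic = r$statistic, estimate = r$estimate,
               ci_low = r$ci_low %||% NA_real_,
               ci_high = r$ci_high %||% NA_real_,
               p_value = r$p_value %||% NA_real_,
               n_resamples = r$n_resamples, seed = r$seed %||% NA_integer_,
               stringsAsFactors = FALSE)
  }))
}

#' Read back a results CSV written by \code{write_results}
#'
#' @param path file path.
#' @return data.frame with one row per statistic.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
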