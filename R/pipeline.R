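# End-to-end orchestration: simulate or read a colony, fit the analysis,
# and write the full report bundle (rates, windowed rates, results table,
# markdown summary, manifest) reproducibly under one seed.

#' Run the whole pipeline as one reproducible job
#'
#' Takes a run configuration (an R list, or a path to a YAML file with the
#' same fields), obtains the colony either by simulation (\code{sim}: a
#' list of \code{\link{sim_config}} arguments) or from CSV files
#' (\code{input_dir}) -- exactly one of the two -- fits
#' \code{\link{analyze_colony}}, and writes into \code{out_dir}:
#' \describe{
#'   \item{\code{colony/}}{the colony CSV set (simulated runs only).}
#'   \item{\code{rates.csv}}{per-dyad, per-phase log rates.}
#'   \item{\code{windowed_rates.csv}}{the windowed time course
#'     (\code{window_days}, default 7).}
#'   \item{\code{results.csv}}{one row per statistic.}
#'   \item{\code{summary.md}}{human-readable summary.}
#'   \item{\code{manifest.json}}{config, seed, package version, config
#'     hash -- everything needed to reproduce the numbers.}
#' }
#' On failure all partial outputs created by the run are removed.
#'
#' @param config list or YAML file path. Recognised fields: \code{sim},
#'   \code{input_dir}, \code{out_dir} (required), \code{filter},
#'   \code{n_boot}, \code{n_perm}, \code{level}, \code{seed},
#'   \code{window_days}.
#' @return The \code{\link{analyze_colony}} fit, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs needs the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config$out_dir is required",
                                    call. = FALSE)
  has_sim <- !is.null(config$sim)
  has_dir <- !is.null(config$input_dir)
  if (has_sim == has_dir) {
    stop("supply exactly one of config$sim and config$input_dir",
         call. = FALSE)
  }
  n_boot <- config$n_boot %||% 5000
  n_perm <- config$n_perm %||% 5000
  level <- config$level %||% 0.95
  seed <- config$seed %||% 1
  window_days <- config$window_days %||% 7

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  made <- character(0)
  note <- function(path) {
    made <<- c(made, path)
    path
  }

  run <- function() {
    if (has_sim) {
      sim <- config$sim
      if (is.null(sim$seed)) sim$seed <- seed
      cfg <- do.call(sim_config, sim)
      col <- generate_colony(cfg)
      write_colony(col, note(file.path(out_dir, "colony")))
    } else {
      col <- read_colony(config$input_dir)
      cfg <- NULL
    }
    fit <- analyze_colony(col, n_boot = n_boot, n_perm = n_perm,
                          level = level, seed = seed,
                          filter = config$filter)
    write_csv_exact(phase_rates(fit$colony),
                    note(file.path(out_dir, "rates.csv")))
    write_csv_exact(windowed_rates(fit$colony, window_days),
                    note(file.path(out_dir, "windowed_rates.csv")))
    write_results(fit, note(file.path(out_dir, "results.csv")))
    write_summary_md(fit, note(file.path(out_dir, "summary.md")))
    write_manifest(config, seed, note(file.path(out_dir, "manifest.json")))
    message("run_pipeline: outputs written to ", out_dir)
    fit
  }
  fit <- tryCatch(run(), error = function(e) {
    unlink(made, recursive = TRUE)
    stop(e)
  })
  invisible(fit)
}

#' @keywords internal
#' @noRd
write_summary_md <- function(fit, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  out <- function(...) writeLines(sprintf(...), con)
  out("# Forced-proximity analysis summary")
  out("")
  if (!is.null(fit$settings$filter)) {
    out("Robustness filter(s): %s",
        paste(fit$settings$filter, collapse = ", "))
    out("")
  }
  out("Dyads: %d test, %d control, %d familiar.",
      fit$dyad_counts["TEST"], fit$dyad_counts["CONTROL"],
      fit$dyad_counts["FAMILIAR"])
  out("")
  out("## Mean change in allogrooming log rate (post - pre)")
  out("")
  for (nm in c("test", "control", "familiar")) {
    r <- fit$group[[nm]]
    if (is.null(r)) next
    out("- %s dyads: %.3f log s/h [%.3f, %.3f]", nm, r$estimate, r$ci_low,
        r$ci_high)
  }
  if (!is.null(fit$permutation)) {
    out("- test - control difference: %.3f log s/h, permutation p = %.4g (%s null, %d resamples)",
        fit$permutation$estimate, fit$permutation$p_value,
        if (isTRUE(fit$permutation$extra$exhaustive)) "exhaustive"
        else "Monte-Carlo",
        fit$permutation$n_resamples)
  }
  out("")
  out("## Partner-preference shift and trade-off")
  out("")
  out("- proportion of grooming to unfamiliar partners, mean change: %.3f [%.3f, %.3f]",
      fit$proportion$estimate, fit$proportion$ci_low, fit$proportion$ci_high)
  out("- trade-off correlation (familiar vs new): r = %.2f [%.2f, %.2f], p = %.3g",
      fit$tradeoff$estimate, fit$tradeoff$ci_low, fit$tradeoff$ci_high,
      fit$tradeoff$p_value)
  out("")
  out("## Test-dyad follow-up models")
  out("")
  fp <- fit$phase_cor$forced_post
  fr <- fit$phase_cor$forced_pre
  out("- Spearman rho forced vs post: %.2f (p = %.3g); forced vs pre: %.2f (p = %.3g)",
      fp$estimate, fp$p_value, fr$estimate, fr$p_value)
  out("- rank model change ~ forced: beta = %.2f, p = %.3g, permutation p = %.3g",
      fit$rank_change$estimate, fit$rank_change$extra$parametric_p,
      fit$rank_change$p_value)
  out("- rank model post ~ pre + forced: beta = %.2f, p = %.3g, permutation p = %.3g",
      fit$rank_post$estimate, fit$rank_post$extra$parametric_p,
      fit$rank_post$p_value)
  out("")
  out("Settings: n_boot = %d, n_perm = %d, level = %.2f, seed = %d.",
      fit$settings$n_boot, fit$settings$n_perm, fit$settings$level,
      fit$settings$seed)
  invisible(path)
}

# FNV-1a hash of a string, reported as 8 hex digits; enough to detect a
# changed config in the manifest.
#' @keywords internal
#' @noRd
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' @keywords internal
#' @noRd
write_manifest <- function(config, seed, path) {
  manifest <- list(
    package = "proxbond",
    version = as.character(utils::packageVersion("proxbond")),
    seed = seed,
    config = config,
    config_hash = config_hash(config))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
  } else {
    writeLines(paste(deparse(manifest), collapse = "\n"), path)
  }
  invisible(path)
}
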