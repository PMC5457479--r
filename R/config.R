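RUNCONFIG_KEYS <- c("scenario", "horizon", "output_step", "rtol", "atol",
                    "seed", "out_dir")

#' Load a run configuration
#'
#' Plain key-value (`key = value`) configuration over documented defaults:
#' `scenario` (default `wild_type_gv`), `horizon` (480 min), `output_step`
#' (1 min), `rtol` (1e-8), `atol` (1e-10), `seed` (1), `out_dir` (`"."`),
#' plus any of the 21 model parameter symbols as scenario overrides.
#' Unknown keys are rejected by name; an empty file yields pure defaults.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return a `meio_config`: list with `scenario`, `overrides` (named
#'   numeric), `horizon`, `outputStep`, `rtol`, `atol`, `seed`, `outDir`,
#'   and `params` (the fully-resolved `meio_params`).
#' @export
loadRunConfig <- function(path = NULL) {
  cfg <- list(scenario = "wild_type_gv", overrides = numeric(0),
              horizon = 480, outputStep = 1, rtol = 1e-8, atol = 1e-10,
              seed = 1, outDir = ".")
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (line in lines) {
      if (!grepl("=", line, fixed = TRUE))
        stop("malformed config line (expected 'key = value'): ", line)
      key <- trimws(sub("=.*$", "", line))
      val <- trimws(sub("^[^=]*=", "", line))
      if (key %in% PARAM_NAMES) {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) stop("non-numeric value for key: ", key)
        cfg$overrides[key] <- num
      } else if (key == "scenario") {
        cfg$scenario <- match.arg(val, SCENARIO_NAMES)
      } else if (key == "out_dir") {
        cfg$outDir <- val
      } else if (key %in% RUNCONFIG_KEYS) {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) stop("non-numeric value for key: ", key)
        slot <- c(horizon = "horizon", output_step = "outputStep",
                  rtol = "rtol", atol = "atol", seed = "seed")[key]
        cfg[[slot]] <- num
      } else {
        stop("unknown config key: ", key)
      }
    }
  }
  if (cfg$horizon < 0) stop("negative horizon")
  base <- scenarioParams(cfg$scenario)
  if (length(cfg$overrides)) base[names(cfg$overrides)] <- cfg$overrides
  validateParams(base)
  cfg$params <- base
  structure(cfg, class = "meio_config")
}

#' Write a scenario report to a directory
#'
#' Deterministic file naming: for each scenario result, a trajectory CSV
#' (`<name>_trajectory.csv`) and a metrics CSV (`<name>_metrics.csv`);
#' across results, a comparison table when there are two or more; plus a
#' `manifest.csv` listing every file with the package version, seeds and
#' integrator tolerances. The fully-resolved config, when given, is echoed
#' to `config_resolved.conf`.
#'
#' @param results nonempty list of `meio_scenario` objects.
#' @param outDir output directory (created if needed).
#' @param config optional `meio_config` to echo.
#' @return the manifest data.frame, invisibly.
#' @export
writeReport <- function(results, outDir, config = NULL) {
  if (!length(results)) stop("results must be nonempty")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("unwritable output directory: ", outDir)
  files <- character(0)
  for (r in results) {
    trajFile <- file.path(outDir, paste0(r$name, "_trajectory.csv"))
    writeTrajectory(r$trajectory, trajFile)
    metrFile <- file.path(outDir, paste0(r$name, "_metrics.csv"))
    m <- r$metrics
    utils::write.csv(data.frame(
      scenario = r$name, commitmentTime = m$commitmentTime,
      cdk1RiseTime = m$cdk1RiseTime, peakCdk1 = m$peakCdk1,
      finalCdk1 = m$finalState[["Cdk1"]],
      finalCdh1 = m$finalState[["Cdh1"]]),
      metrFile, row.names = FALSE, quote = FALSE)
    files <- c(files, trajFile, metrFile)
  }
  if (length(results) >= 2) {
    cmpFile <- file.path(outDir, "comparison.csv")
    utils::write.csv(compareScenarios(results), cmpFile,
                     row.names = FALSE, quote = FALSE)
    files <- c(files, cmpFile)
  }
  if (!is.null(config)) {
    cfgFile <- file.path(outDir, "config_resolved.conf")
    lines <- c(
      sprintf("scenario = %s", config$scenario),
      sprintf("horizon = %g", config$horizon),
      sprintf("output_step = %g", config$outputStep),
      sprintf("rtol = %g", config$rtol),
      sprintf("atol = %g", config$atol),
      sprintf("seed = %g", config$seed),
      sprintf("%s = %s", names(config$overrides),
              vapply(config$overrides, format, character(1), digits = 15))
    )
    writeLines(lines, cfgFile)
    files <- c(files, cfgFile)
  }
  manifest <- data.frame(
    file = basename(files),
    package_version = as.character(utils::packageVersion("meioswitch")),
    seed = if (!is.null(config)) config$seed else NA,
    rtol = if (!is.null(config)) config$rtol else 1e-8,
    atol = if (!is.null(config)) config$atol else 1e-10
  )
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
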