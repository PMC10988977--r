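# Machine-readable outputs: results table, validation JSON, CE-plane
# CSV, run manifest.

suite_table <- function(suite) {
  stopifnot(inherits(suite, "apbi_cea"))
  do.call(rbind, lapply(names(ANALYSES), function(nm) {
    res <- suite[[nm]]
    tab <- res$table
    rbind(
      data.frame(analysis = nm, measure = tab$measure,
                 iort = tab$evaluated, imrt = tab$comparator,
                 incremental = tab$incremental, icer = tab$icer,
                 dominance = tab$dominance),
      data.frame(analysis = nm, measure = "COST",
                 iort = res$cost_evaluated, imrt = res$cost_comparator,
                 incremental = res$incremental_cost, icer = NA_real_,
                 dominance = NA_character_))
  }))
}

#' Write all artifacts of an analysis suite to a directory
#'
#' Writes `results.csv` (one row per analysis x measure, mirroring the
#' published results-table layout plus a cost row), `validation.json`
#' (per-arm 10-year cumulative recurrence and overall survival),
#' `ce_plane.csv` (incremental benefit/cost coordinates per analysis and
#' measure) and `manifest.json` (package version, convention set,
#' config hash, timestamp, file list).
#'
#' @param suite An [apbi_cea()] result.
#' @param dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_suite <- function(suite, dir) {
  stopifnot(inherits(suite, "apbi_cea"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  f <- file.path(dir, "results.csv")
  utils::write.csv(suite_table(suite), f, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(dir, "validation.json")
  jsonlite::write_json(suite$validation, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)

  f <- file.path(dir, "ce_plane.csv")
  pts <- do.call(rbind, lapply(names(ANALYSES), function(nm)
    cbind(analysis = nm, ce_plane(suite[[nm]]))))
  utils::write.csv(pts, f, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(dir, "config.yaml")
  cfg <- suite$config
  cfg$conventions <- unclass(cfg$conventions)
  yaml::write_yaml(unclass(cfg), f)
  files <- c(files, f)

  manifest <- list(
    package = "apbicea",
    version = as.character(utils::packageVersion("apbicea")),
    config_hash = unname(tools::md5sum(f)),
    conventions = unclass(suite$config$conventions),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = basename(c(files, file.path(dir, "manifest.json"))))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, mf)
  invisible(files)
}

#' Write a convention-calibration report
#'
#' @param calibration A [calibrate_conventions()] result.
#' @param dir Output directory.
#' @return Files written, invisibly (`calibration.csv` with the full
#'   score table and `conventions.yaml` with the selected set).
#' @export
write_calibration <- function(calibration, dir) {
  stopifnot(inherits(calibration, "convention_calibration"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "calibration.csv")
  utils::write.csv(calibration$scores, f1, row.names = FALSE)
  f2 <- file.path(dir, "conventions.yaml")
  yaml::write_yaml(unclass(calibration$best), f2)
  invisible(c(f1, f2))
}
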