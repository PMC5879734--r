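#' Write a cohort to disk
#'
#' CSV format: one row per (patient, segment) with the fixed header
#' `patient_id,segment,helical_lr,...,phase50_si` (mm, full precision), and a
#' companion lung CSV `patient_id,state,left_ml,right_ml,total_ml`.  The JSON
#' format mirrors both tables in one file.  Values round-trip bit-exactly
#' through [read_cohort()].
#'
#' @param cohort A `liver_cohort` (or cohort point table).
#' @param path Output file; extension `.csv` or `.json` selects the format.
#' @param lung_path Lung CSV path; default replaces `.csv` with `_lungs.csv`.
#'   Ignored for JSON output.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, lung_path = NULL) {
  if (!inherits(cohort, "liver_cohort")) cohort <- as_liver_cohort(cohort)
  fmt <- file_format(path)
  if (fmt == "csv") {
    readr::write_csv(full_precision(cohort$points), path)
    if (is.null(lung_path)) lung_path <- default_lung_path(path)
    if (nrow(cohort$lungs)) {
      readr::write_csv(full_precision(cohort$lungs), lung_path)
    }
  } else {
    obj <- list(points = cohort$points, lungs = cohort$lungs)
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a cohort from disk
#'
#' Reads a cohort written by [write_cohort()] (CSV with companion lung CSV,
#' or the JSON mirror) and validates the cohort invariants: every patient
#' must carry all nine segments exactly once, and all coordinates must parse
#' as finite numbers.  Schema violations raise an error naming the patient
#' and segment; malformed numbers raise a parse error with the offending row.
#' Row order is normalized to patient, then segment in canonical order, so a
#' write/read round trip is bit-exact.
#'
#' @param path Cohort file (`.csv` or `.json`).
#' @param lung_path Optional lung CSV; default looks for the companion file
#'   next to `path` (CSV only) and is skipped when absent.
#' @return A `liver_cohort`.
#' @export
read_cohort <- function(path, lung_path = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  fmt <- file_format(path)
  if (fmt == "csv") {
    points <- read_checked_csv(path, char_cols = c("patient_id", "segment"))
    if (is.null(lung_path)) {
      cand <- default_lung_path(path)
      lung_path <- if (file.exists(cand)) cand else NA_character_
    }
    lungs <- NULL
    if (!is.na(lung_path)) {
      lungs <- read_checked_csv(lung_path, char_cols = c("patient_id", "state"))
    }
  } else {
    obj <- jsonlite::fromJSON(path)
    # whole-number coordinates come back as integers; keep doubles throughout
    as_double_cols <- function(df, char_cols) {
      for (nm in setdiff(names(df), char_cols)) df[[nm]] <- as.double(df[[nm]])
      df
    }
    points <- as_double_cols(as_tibble(obj$points), c("patient_id", "segment"))
    lungs <- if (!is.null(obj$lungs) && length(obj$lungs)) as_tibble(obj$lungs) else NULL
    if (!is.null(lungs) && nrow(lungs) == 0L) lungs <- NULL
    if (!is.null(lungs)) lungs <- as_double_cols(lungs, c("patient_id", "state"))
  }
  as_liver_cohort(points, lungs)
}

file_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("csv", "json")) {
    abort(paste0("unsupported cohort format '.", ext, "' (use .csv or .json)"))
  }
  ext
}

default_lung_path <- function(path) {
  sub("\\.csv$", "_lungs.csv", path, ignore.case = TRUE)
}

# shortest exact decimal representation that survives a write/read round trip
full_precision <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

# read with readr (handles BOM and CRLF), then convert numeric columns with
# base strtod, which is correctly rounded and therefore bit-exact on %.17g
read_checked_csv <- function(path, char_cols) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs)) {
    p <- probs[1, ]
    abort(sprintf("parse error in %s at row %d, column %d: %s",
                  path, p$row, p$col, p$expected))
  }
  for (nm in setdiff(names(df), char_cols)) {
    v <- suppressWarnings(as.double(df[[nm]]))
    bad <- which(is.na(v) & !is.na(df[[nm]]))
    if (length(bad)) {
      abort(sprintf(
        "parse error in %s at row %d (line %d), column '%s': '%s' is not a number",
        path, bad[1], bad[1] + 1L, nm, df[[nm]][bad[1]]
      ))
    }
    df[[nm]] <- v
  }
  df
}

#' Read a run configuration
#'
#' A run configuration makes a whole pipeline run reproducible from one file.
#' YAML (`.yml`/`.yaml`) or JSON.  Recognized fields (all optional except
#' `seed`): `seed`, `n_patients` (default 20), `cohort_csv` / `lung_csv`
#' (read an external cohort instead of simulating), `params` (named overrides
#' passed to [sim_params()], e.g. `helical_mean`), `margin`
#' (`n`, `coverage_t` for [margin_config()]), `coverage` (`enabled`,
#' `n_reps`), `include_traces`, `out_dir`.
#'
#' @param path Config file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort("config must be .yaml/.yml or .json")
  }
  as_run_config(cfg)
}

as_run_config <- function(cfg) {
  if (inherits(cfg, "run_config")) return(cfg)
  if (!is.list(cfg)) abort("config must be a named list")
  if (is.null(cfg$seed)) abort("config requires a `seed`")
  if (!is.numeric(cfg$seed) || cfg$seed != floor(cfg$seed)) {
    abort("`seed` must be an integer")
  }
  defaults <- list(
    n_patients = 20L, cohort_csv = NULL, lung_csv = NULL,
    params = list(), margin = list(), coverage = list(enabled = TRUE, n_reps = 200L),
    include_traces = TRUE, out_dir = "segmotion_out"
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$coverage$enabled)) cfg$coverage$enabled <- TRUE
  if (is.null(cfg$coverage$n_reps)) cfg$coverage$n_reps <- 200L
  known <- c("seed", names(defaults))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read an external cohort) -> amplitude tables for all
#' three state pairs -> margin table -> validation, and writes every artifact
#' under `out_dir`: cohort and lung CSVs, per-pair amplitude CSVs and aligned
#' text tables, the margin CSV and text table, `validation.json`, and
#' `run_log.json` recording the seed, the full configuration, its hash and
#' the package version.  Runs are deterministic: the same configuration
#' produces byte-identical reports.  If a stage fails, a
#' `PIPELINE_FAILED.txt` marker naming the stage is left in `out_dir` and the
#' error is re-thrown.
#'
#' @param config A `run_config`, a named list, or the path of a YAML/JSON
#'   config file (see [read_run_config()]).
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @return Invisibly, a list with the computed objects (`cohort`,
#'   `amplitudes`, `margins`, `validation`) and the written `paths`.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(list(seed = 1, n_patients = 20,
#'                          coverage = list(n_reps = 20)),
#'                     out_dir = tempfile("segmotion"))
#' out$margins
#' }
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  config <- as_run_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fail_marker <- file.path(config$out_dir, "PIPELINE_FAILED.txt")
  if (file.exists(fail_marker)) unlink(fail_marker)
  on_fail <- function(stage, e) {
    writeLines(c(
      paste0("pipeline failed in stage: ", stage),
      "outputs in this directory may be partial",
      conditionMessage(e)
    ), fail_marker)
    abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) on_fail(name, e))
  }

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_csv)) {
      read_cohort(config$cohort_csv, lung_path = config$lung_csv)
    } else {
      params <- do.call(sim_params, config$params)
      generate_cohort(params, n_patients = config$n_patients,
                      seed = config$seed,
                      include_traces = isTRUE(config$include_traces))
    }
  })

  amplitudes <- stage("amplitudes", {
    setNames(lapply(state_pairs(), function(p) amplitude_table(cohort, p)),
             state_pairs())
  })

  margins <- stage("margins", {
    mc <- config$margin
    cfg <- if (length(mc)) {
      margin_config(n = if (is.null(mc$n)) n_patients_of(cohort) else mc$n,
                    coverage_t = mc$coverage_t)
    } else {
      NULL
    }
    margin_table(cohort, cfg)
  })

  validation <- stage("validate", {
    cov <- NULL
    if (isTRUE(config$coverage$enabled)) {
      params <- if (!is.null(cohort$params)) cohort$params else do.call(sim_params, config$params)
      cov <- coverage_simulation(
        params, config = attr(margins, "config"),
        n_patients = n_patients_of(cohort),
        n_reps = config$coverage$n_reps,
        seed = config$seed + 1L
      )
    }
    validation_report(cohort, coverage = cov)
  })

  paths <- stage("write", {
    od <- config$out_dir
    p <- list(cohort = file.path(od, "cohort.csv"))
    write_cohort(cohort, p$cohort)
    for (pr in state_pairs()) {
      p[[paste0("amplitudes_", pr)]] <- file.path(od, paste0("amplitudes_", pr, ".csv"))
      readr::write_csv(as_tibble(amplitudes[[pr]]), p[[paste0("amplitudes_", pr)]])
      txt <- file.path(od, paste0("amplitudes_", pr, ".txt"))
      writeLines(format_amplitude_table(amplitudes[[pr]]), txt)
    }
    p$margins <- file.path(od, "margins.csv")
    readr::write_csv(as_tibble(margins), p$margins)
    writeLines(format_margin_table(margins), file.path(od, "margins.txt"))
    p$validation <- file.path(od, "validation.json")
    jsonlite::write_json(validation, p$validation, digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
    p$run_log <- file.path(od, "run_log.json")
    # the hash (and logged config) exclude the output location, which does
    # not influence any computed number
    cfg_log <- unclass(config)
    cfg_log$out_dir <- NULL
    log <- list(
      seed = config$seed,
      config = cfg_log,
      config_hash = rlang::hash(cfg_log),
      package = "segmotion",
      package_version = as.character(utils::packageVersion("segmotion"))
    )
    jsonlite::write_json(log, p$run_log, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    p
  })

  invisible(list(cohort = cohort, amplitudes = amplitudes, margins = margins,
                 validation = validation, paths = paths, config = config))
}
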