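#' Assemble a run configuration
#'
#' Collects every tunable parameter of the pipeline -- signal processing,
#' spectrum bins, cut-points, PLS components, bootstrap size, seed -- with
#' defaults, optionally overridden by a YAML file and then by `...`
#' (file overrides defaults, arguments override the file).
#'
#' @param path Optional YAML file of overrides.
#' @param ... Named overrides applied last.
#' @return A named list of class `fitpath_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- c(
    signal_config(),
    list(sample_rate = 30, k = 2, B = 500, seed = 1L, conf = 0.95)
  )
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown)) {
      abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
    }
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = c("fitpath_config", "list"))
}

provenance_record <- function(config, seed) {
  list(
    package = "fitpath",
    version = as.character(utils::packageVersion("fitpath")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_hash = rlang::hash(unclass(config))
  )
}

write_provenance <- function(dir, config, seed) {
  jsonlite::write_json(provenance_record(config, seed),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Generate synthetic cohort inputs on disk
#'
#' Wraps [simulate_cohort()] and writes `spectrum.csv`, `panel.csv`, the
#' ground truth (`truth.json`, `latents.csv`) and a provenance record.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()] (its `seed` drives the simulation).
#' @param ... Passed on to [simulate_cohort()] (e.g. `n`, `true_a`).
#' @return Invisibly, the [simulate_cohort()] result.
#' @export
pipeline_simulate <- function(out_dir, config = run_config(), ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(seed = config$seed, ...)
  readr::write_csv(sim$spectrum, file.path(out_dir, "spectrum.csv"))
  readr::write_csv(sim$panel, file.path(out_dir, "panel.csv"))
  readr::write_csv(sim$truth$latents, file.path(out_dir, "latents.csv"))
  jsonlite::write_json(
    sim$truth[c("config", "indirect", "total", "proportion_mediated")],
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  write_provenance(out_dir, config, config$seed)
  invisible(sim)
}

#' Process a directory of raw accelerometer CSVs into a spectrum table
#'
#' Each `*.csv` in `raw_dir` is one subject's recording
#' (`timestamp,x,y,z`, axes in g, named `<subject_id>.csv`).  Unreadable or
#' malformed files are skipped with a message.
#'
#' @param raw_dir Directory of per-subject raw CSVs.
#' @param config A [run_config()] holding the signal parameters
#'   (`sample_rate`, filter band, non-wear rule, bins).
#' @param out Optional path for the combined spectrum CSV.
#' @return Tibble of per-subject spectrum rows (and cut-point summaries as
#'   attribute `"cutpoints"`).
#' @export
pipeline_process_accel <- function(raw_dir, config = run_config(), out = NULL) {
  files <- list.files(raw_dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) abort(sprintf("No raw CSV files found in %s.", raw_dir))
  rows <- list()
  cuts <- list()
  for (f in files) {
    sid <- sub("\\.csv$", "", basename(f))
    res <- tryCatch({
      rec <- read_recording(f, subject_id = sid,
                            sample_rate = config$sample_rate)
      process_recording(rec, config$sample_rate, config)
    }, error = function(e) {
      inform(sprintf("Skipping %s: %s", basename(f), conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      rows[[sid]] <- res$spectrum
      cuts[[sid]] <- res$cutpoints
    }
  }
  if (!length(rows)) abort("No recording could be processed.")
  spectrum <- list_rbind(rows)
  if (!is.null(out)) readr::write_csv(spectrum, out)
  attr(spectrum, "cutpoints") <- list_rbind(cuts)
  spectrum
}

#' Fit the full model suite from spectrum and panel tables
#'
#' Wraps [composite_score()] and [run_study()]; inputs may be file paths or
#' in-memory data frames.  Errors on schema mismatches name the missing
#' columns.
#'
#' @param spectrum Spectrum table or CSV path ([summarize_days()] schema).
#' @param panel Clinical panel table or CSV path.
#' @param config A [run_config()] (uses `k`, `B`, `seed`, `conf`).
#' @param out_dir Optional directory for the results bundle
#'   ([write_study()] layout plus provenance).
#' @return The [run_study()] result.
#' @export
pipeline_fit <- function(spectrum, panel, config = run_config(),
                         out_dir = NULL) {
  if (is.character(spectrum)) {
    spectrum <- readr::read_csv(spectrum, show_col_types = FALSE)
  }
  if (is.character(panel)) {
    panel <- readr::read_csv(panel, show_col_types = FALSE)
  }
  need <- c("subject_id", "waist", "sbp", "tc", "hdl", "tg", "hba1c", "crf",
            "sex", "age")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    abort(paste0("Panel is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  study <- run_study(spectrum, panel, k = config$k, B = config$B,
                     seed = config$seed, conf = config$conf)
  if (!is.null(out_dir)) {
    write_study(study, out_dir)
    write_provenance(out_dir, config, config$seed)
  }
  study
}
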