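#' Default indicator columns of the physical-activity block
#'
#' The 22 intensity-spectrum bins plus non-wear time (non-wear, mostly
#' sleep, is carried as its own behaviour variable in the activity pattern).
#'
#' @param edges Spectrum bin edges in mg.
#' @return Character vector of indicator column names.
#' @export
pa_block <- function(edges = spectrum_edges()) {
  c(spectrum_bin_names(edges), "nonwear")
}

#' The seven structural models of the activity--fitness--health analysis
#'
#' Returns one of seven pre-specified PLS path models over the constructs
#' PA (higher-order composite of the intensity-spectrum block), CRF
#' (cardiorespiratory fitness), CS (cardiometabolic composite score) and the
#' sex and age covariates:
#'
#' 1. `PA -> CS` (simple association).
#' 2. `PA -> CS`, controlling CS for sex and age.
#' 3. `PA -> CRF`.
#' 4. `PA -> CRF`, controlling CRF for sex and age.
#' 5. `CRF -> CS`, controlling CS for sex and age (no PA).
#' 6. Mediation: `PA -> CRF -> CS` plus the direct `PA -> CS`, with sex and
#'    age paths into both CRF and CS.
#' 7. Model 6 plus a `sex:CRF -> CS` interaction (moderation check).
#'
#' Covariates enter only as predictors of the endogenous constructs (they do
#' not predict PA).
#'
#' @param id Model number, 1 to 7.
#' @param bins Indicator columns of the PA block (default [pa_block()]).
#' @param k Number of underlying PLS components of the PA composite.
#' @return A [pls_model()] specification.
#' @export
study_model <- function(id, bins = pa_block(), k = 2) {
  if (!id %in% 1:7) abort("`id` must be one of 1..7.")
  PA <- composite(bins, k = k)
  switch(as.character(id),
    "1" = pls_model(PA = PA, CS = "cs", paths = "PA -> CS"),
    "2" = pls_model(PA = PA, CS = "cs", sex = "sex", age = "age",
                    paths = c("PA -> CS", "sex -> CS", "age -> CS")),
    "3" = pls_model(PA = PA, CRF = "crf", paths = "PA -> CRF"),
    "4" = pls_model(PA = PA, CRF = "crf", sex = "sex", age = "age",
                    paths = c("PA -> CRF", "sex -> CRF", "age -> CRF")),
    "5" = pls_model(CRF = "crf", CS = "cs", sex = "sex", age = "age",
                    paths = c("CRF -> CS", "sex -> CS", "age -> CS")),
    "6" = pls_model(PA = PA, CRF = "crf", CS = "cs", sex = "sex", age = "age",
                    paths = c("PA -> CRF", "PA -> CS", "CRF -> CS",
                              "sex -> CRF", "age -> CRF",
                              "sex -> CS", "age -> CS")),
    "7" = pls_model(PA = PA, CRF = "crf", CS = "cs", sex = "sex", age = "age",
                    paths = c("PA -> CRF", "PA -> CS", "CRF -> CS",
                              "sex -> CRF", "age -> CRF",
                              "sex -> CS", "age -> CS"),
                    interactions = "sex:CRF -> CS")
  )
}

#' Product-of-coefficients mediation arithmetic
#'
#' Given the standardised paths exposure -> mediator (`a`), mediator ->
#' outcome (`b`) and the direct exposure -> outcome path (`c_direct`),
#' computes the indirect association `a * b`, the total association
#' `c_direct + a * b` and the proportion mediated `indirect / total`.
#'
#' @param a,b,c_direct Standardised path coefficients.
#' @return A tibble with one row per quantity (`a`, `b`, `c_direct`,
#'   `indirect`, `total`, `proportion_mediated`) and its `estimate`.  The
#'   proportion is `NA` when the total is zero, and a consistency warning is
#'   issued when indirect and total effects have opposite signs (the
#'   proportion then falls outside `[0, 1]`).
#' @examples
#' mediation_effects(a = 0.387, b = 0.563, c_direct = 0.047)
#' @export
mediation_effects <- function(a, b, c_direct) {
  indirect <- a * b
  total <- c_direct + indirect
  if (total == 0) {
    warn("Total association is zero; proportion mediated undefined.")
    prop <- NA_real_
  } else {
    prop <- indirect / total
    if (indirect != 0 && sign(indirect) != sign(total)) {
      warn("Indirect and total associations have opposite signs; proportion mediated falls outside [0, 1].")
    }
  }
  tibble(
    quantity = c("a", "b", "c_direct", "indirect", "total",
                 "proportion_mediated"),
    estimate = c(a, b, c_direct, indirect, total, prop)
  )
}

#' Decompose the exposure--outcome association through a mediator
#'
#' Extracts the `a` (exposure -> mediator), `b` (mediator -> outcome) and
#' direct (exposure -> outcome) paths from a fitted mediation model and
#' applies [mediation_effects()].  When the fit carries bootstrap replicates
#' every derived quantity is recomputed per replicate, giving percentile
#' confidence intervals for the indirect and total effects and the
#' proportion mediated as well as for the raw paths.
#'
#' @param fit A `pls_sem` fit containing the three paths (e.g. study model 6
#'   or 7).
#' @param exposure,mediator,outcome Construct names.
#' @return A tibble of class `pls_mediation` (columns `quantity`,
#'   `estimate`, and `conf.low`/`conf.high` when bootstrapped).
#' @export
decompose_mediation <- function(fit, exposure = "PA", mediator = "CRF",
                                outcome = "CS") {
  stopifnot(inherits(fit, "pls_sem"))
  pull_path <- function(paths, est, from, to) {
    i <- which(paths$from == from & paths$to == to)
    if (!length(i)) {
      abort(sprintf("Fit has no `%s -> %s` path.", from, to))
    }
    est[i]
  }
  a <- pull_path(fit$paths, fit$paths$estimate, exposure, mediator)
  b <- pull_path(fit$paths, fit$paths$estimate, mediator, outcome)
  cd <- pull_path(fit$paths, fit$paths$estimate, exposure, outcome)
  out <- mediation_effects(a, b, cd)
  if (!is.null(fit$boot)) {
    nm <- colnames(fit$boot$paths)
    ab <- fit$boot$paths[, paste(exposure, "->", mediator)]
    bb <- fit$boot$paths[, paste(mediator, "->", outcome)]
    cb <- fit$boot$paths[, paste(exposure, "->", outcome)]
    reps <- cbind(
      a = ab, b = bb, c_direct = cb, indirect = ab * bb,
      total = cb + ab * bb,
      proportion_mediated = (ab * bb) / (cb + ab * bb)
    )
    ci <- boot_ci(reps, fit$boot$conf)
    out$conf.low <- ci[, 1]
    out$conf.high <- ci[, 2]
  }
  structure(out, class = c("pls_mediation", class(out)),
            exposure = exposure, mediator = mediator, outcome = outcome)
}

#' Run the full seven-model analysis on a cohort
#'
#' Joins a per-person intensity-spectrum table with the clinical panel,
#' builds the reversed cardiometabolic composite score, fits all seven
#' structural models with bootstrap confidence intervals, extracts the
#' activity-pattern profile of every model containing the PA block, and
#' decomposes the mediation through fitness from model 6.
#'
#' Only spectrum rows with `valid = TRUE` are analysed; spectrum/panel join
#' mismatches are reported and excluded.  Sex may be coded 0/1 (female = 0,
#' male = 1) or as `"female"`/`"male"` strings.
#'
#' @param spectrum Output of [summarize_days()] (or the same schema).
#' @param panel Clinical panel with `subject_id`, `waist`, `sbp`, `tc`,
#'   `hdl`, `tg`, `hba1c`, `crf`, `sex`, `age`.
#' @param k PLS components of the PA composite (default 2).
#' @param B Bootstrap replicates per model.
#' @param seed Integer seed for the bootstrap resampling.
#' @param conf Confidence level.
#' @param models Which of the seven models to fit (default all).
#' @return An object of class `pls_study`: list with `fits` (named
#'   `model_1` ... `model_7`), `mediation`, `patterns`, `data`, `summary`
#'   (tibble of headline quantities) and the run settings.
#' @export
run_study <- function(spectrum, panel, k = 2, B = 500, seed = NULL,
                      conf = 0.95, models = 1:7) {
  spectrum <- as_tibble(spectrum)
  panel <- as_tibble(panel)
  if (!"subject_id" %in% names(spectrum) || !"subject_id" %in% names(panel)) {
    abort("Both tables must be keyed by `subject_id`.")
  }
  if ("valid" %in% names(spectrum)) {
    n_invalid <- sum(!spectrum$valid)
    if (n_invalid) {
      inform(sprintf("Excluding %d subject(s) without a valid measurement.",
                     n_invalid))
    }
    spectrum <- spectrum[spectrum$valid, , drop = FALSE]
  }
  unmatched <- c(setdiff(spectrum$subject_id, panel$subject_id),
                 setdiff(panel$subject_id, spectrum$subject_id))
  if (length(unmatched)) {
    inform(sprintf("Excluding %d subject(s) present in only one table.",
                   length(unmatched)))
  }
  cs <- composite_score(panel)
  data <- spectrum |>
    inner_join(panel, by = "subject_id") |>
    inner_join(cs, by = "subject_id")
  if (nrow(data) == 0L) abort("No subjects remain after joining the tables.")
  if (is.character(data$sex) || is.factor(data$sex)) {
    data$sex <- as.integer(as.character(data$sex) == "male")
  }
  bins <- intersect(pa_block(), names(data))
  if (length(bins) < 2L) abort("Spectrum table lacks the intensity-bin columns.")

  fits <- list()
  for (id in models) {
    m <- study_model(id, bins = bins, k = k)
    fits[[paste0("model_", id)]] <- bootstrap_pls(
      data, m, B = B, conf = conf,
      seed = if (is.null(seed)) NULL else seed + id
    )
  }
  patterns <- imap(
    fits[vapply(fits, function(f) "PA" %in% names(f$model$constructs), logical(1))],
    function(f, nm) pattern_profile(f, data, "PA")
  )
  mediation <- if ("model_6" %in% names(fits)) {
    decompose_mediation(fits$model_6)
  }
  summary <- study_summary(fits, mediation)
  structure(
    list(fits = fits, mediation = mediation, patterns = patterns,
         data = data, summary = summary,
         settings = list(k = k, B = B, seed = seed, conf = conf)),
    class = "pls_study"
  )
}

study_summary <- function(fits, mediation) {
  path_rows <- imap(fits, function(f, nm) {
    tidy(f) |> mutate(model = nm, .before = 1) |> select(!any_of(c("from", "to")))
  }) |> list_rbind()
  r2_rows <- imap(fits, function(f, nm) {
    f$r2 |> mutate(model = nm, term = paste0("R2_", .data$construct),
                   estimate = .data$r2, .keep = "none") |>
      select("model", "term", "estimate")
  }) |> list_rbind()
  med_rows <- if (!is.null(mediation)) {
    as_tibble(mediation) |>
      mutate(model = "model_6", term = .data$quantity) |>
      select(!"quantity") |>
      select("model", "term", everything())
  }
  bind_rows(path_rows, r2_rows, med_rows)
}

#' @export
print.pls_study <- function(x, ...) {
  cat(sprintf("Seven-model PLS-SEM study (n = %d, k = %d, B = %d)\n",
              nrow(x$data), x$settings$k, x$settings$B))
  if (!is.null(x$mediation)) {
    cat("Mediation through CRF (model 6):\n")
    print(as.data.frame(x$mediation), row.names = FALSE)
  }
  invisible(x)
}

#' Write a study results bundle to disk
#'
#' One directory per model with `paths.csv`, `r2.csv` and (where the model
#' contains the PA block) `pattern.csv`; `mediation.json` and a
#' `summary.json` of headline quantities at the top level.
#'
#' @param study A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "pls_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study$fits)) {
    mdir <- file.path(dir, nm)
    dir.create(mdir, showWarnings = FALSE)
    readr::write_csv(tidy(study$fits[[nm]]), file.path(mdir, "paths.csv"))
    readr::write_csv(study$fits[[nm]]$r2, file.path(mdir, "r2.csv"))
    if (nm %in% names(study$patterns)) {
      readr::write_csv(as_tibble(study$patterns[[nm]]),
                       file.path(mdir, "pattern.csv"))
    }
  }
  if (!is.null(study$mediation)) {
    jsonlite::write_json(as.list(as_tibble(study$mediation)),
                         file.path(dir, "mediation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  readr::write_csv(study$summary, file.path(dir, "summary.csv"))
  jsonlite::write_json(
    split(study$summary$estimate,
          paste(study$summary$model, study$summary$term, sep = ".")),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(dir)
}
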