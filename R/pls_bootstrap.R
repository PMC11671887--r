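#' Percentile bootstrap for a PLS path model
#'
#' Resamples subjects with replacement, refits the full two-stage model on
#' each replicate and stores the replicate draws of every structural path,
#' every composite indicator weight, every R-squared and the per-indicator
#' pattern values (square-root selectivity fraction and multivariate
#' covariance).  Replicate composites are oriented exactly as in the point
#' fit -- non-negative correlation with their stage-1 target -- so path signs
#' are comparable across replicates.  Percentile confidence intervals are
#' attached and surface through [tidy.pls_sem()], [pattern_profile()] and
#' [decompose_mediation()].
#'
#' Replicates whose refit fails are dropped and counted; more than 5%
#' failures is an error.
#'
#' @inheritParams fit_pls
#' @param B Number of bootstrap replicates (at least 100).
#' @param seed Optional integer seed for reproducible resampling.
#' @param conf Confidence level for the percentile intervals.
#' @return A `pls_sem` fit with a `boot` element (replicate matrices, `B`,
#'   `n_fail`, `conf`, `seed`).
#' @export
bootstrap_pls <- function(data, model, B = 1000, seed = NULL, conf = 0.95) {
  if (B < 100) abort("Use at least 100 bootstrap replicates.")
  fit <- fit_pls(data, model)
  data <- as.data.frame(data)
  data <- data[stats::complete.cases(
    data[unique(unlist(map(model$constructs, "indicators")))]
  ), , drop = FALSE]
  n <- nrow(data)
  if (!is.null(seed)) set.seed(seed)

  path_names <- paste(fit$paths$from, "->", fit$paths$to)
  comps <- names(model$constructs)[
    vapply(model$constructs, function(c) c$type == "composite", logical(1))
  ]
  wkey <- paste(fit$weights$construct, fit$weights$indicator)

  paths_b <- matrix(NA_real_, B, length(path_names),
                    dimnames = list(NULL, path_names))
  r2_b <- matrix(NA_real_, B, nrow(fit$r2), dimnames = list(NULL, fit$r2$construct))
  w_b <- matrix(NA_real_, B, length(wkey), dimnames = list(NULL, wkey))
  pat_b <- lapply(setNames(comps, comps), function(nm) {
    ind <- model$constructs[[nm]]$indicators
    list(sqrt_sel = matrix(NA_real_, B, length(ind), dimnames = list(NULL, ind)),
         mv_cov = matrix(NA_real_, B, length(ind), dimnames = list(NULL, ind)))
  })

  n_fail <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rb <- tryCatch(
      suppressMessages(suppressWarnings(fit_pls(data[idx, , drop = FALSE], model))),
      error = function(e) NULL
    )
    if (is.null(rb)) {
      n_fail <- n_fail + 1L
      next
    }
    paths_b[b, paste(rb$paths$from, "->", rb$paths$to)] <- rb$paths$estimate
    r2_b[b, rb$r2$construct] <- rb$r2$r2
    if (nrow(rb$weights)) {
      w_b[b, paste(rb$weights$construct, rb$weights$indicator)] <- rb$weights$weight
    }
    for (nm in comps) {
      pv <- pattern_values(rb, data[idx, , drop = FALSE], nm)
      pat_b[[nm]]$sqrt_sel[b, pv$indicator] <- pv$sqrt_selectivity
      pat_b[[nm]]$mv_cov[b, pv$indicator] <- pv$mv_covariance
    }
  }
  if (n_fail > 0.05 * B) {
    abort(sprintf("Bootstrap failed in %d of %d replicates.", n_fail, B))
  }
  keep <- !apply(paths_b, 1, function(r) all(is.na(r)))
  fit$boot <- list(
    paths = paths_b[keep, , drop = FALSE],
    r2 = r2_b[keep, , drop = FALSE],
    weights = w_b[keep, , drop = FALSE],
    pattern = lapply(pat_b, function(p) list(
      sqrt_sel = p$sqrt_sel[keep, , drop = FALSE],
      mv_cov = p$mv_cov[keep, , drop = FALSE]
    )),
    B = B, n_fail = n_fail, conf = conf, seed = seed
  )
  fit
}

# raw pattern computation for one composite on one data set
pattern_values <- function(fit, data, construct) {
  ind <- fit$model$constructs[[construct]]$indicators
  score <- fit$scores[[construct]]
  X <- as.matrix(as.data.frame(data)[ind])
  s <- apply(X, 2, sd)
  sqrt_sel <- rep(0, length(ind))
  ok <- is.finite(s) & s > 0
  sqrt_sel[ok] <- abs(cor(X[, ok, drop = FALSE], score))
  mv_cov <- as.vector(cov(X, score))
  mv_cov[!ok] <- 0
  tibble(indicator = ind, sqrt_selectivity = sqrt_sel, mv_covariance = mv_cov)
}

#' Intensity-pattern profile of a composite construct
#'
#' For each indicator of a composite block, reports the square-root
#' selectivity fraction -- the absolute correlation between the standardised
#' indicator and the composite score, whose square is the fraction of that
#' indicator's variance explained by the construct (standardised
#' contribution) -- and the multivariate covariance coefficient, the
#' covariance between the raw indicator (min/day) and the standardised
#' composite score (the pattern in original units).
#'
#' @param fit A `pls_sem` fit (bootstrapped fits yield confidence intervals).
#' @param data The data the fit was estimated on (raw indicator columns).
#' @param construct Name of the composite construct; defaults to the first.
#' @return A tibble of class `pls_pattern`: `indicator`,
#'   `sqrt_selectivity`, `mv_covariance` (+ `*_low`/`*_high` percentile
#'   bounds when bootstrapped).  Zero-variance indicators get value 0 with a
#'   warning.
#' @export
pattern_profile <- function(fit, data, construct = NULL) {
  stopifnot(inherits(fit, "pls_sem"))
  comps <- names(fit$model$constructs)[
    vapply(fit$model$constructs, function(c) c$type == "composite", logical(1))
  ]
  if (!length(comps)) abort("Model has no composite construct.")
  construct <- construct %||% comps[1]
  if (!construct %in% comps) abort(sprintf("`%s` is not a composite.", construct))
  data <- as.data.frame(data)
  data <- data[stats::complete.cases(
    data[unique(unlist(map(fit$model$constructs, "indicators")))]
  ), , drop = FALSE]
  ind <- fit$model$constructs[[construct]]$indicators
  s <- apply(as.matrix(data[ind]), 2, sd)
  if (any(!is.finite(s) | s == 0)) {
    warn(paste0("Zero-variance indicator(s) reported as 0: ",
                paste(ind[!is.finite(s) | s == 0], collapse = ", ")))
  }
  out <- pattern_values(fit, data, construct)
  if (!is.null(fit$boot)) {
    pb <- fit$boot$pattern[[construct]]
    ci_s <- boot_ci(pb$sqrt_sel, fit$boot$conf)
    ci_c <- boot_ci(pb$mv_cov, fit$boot$conf)
    out$sqrt_selectivity_low <- ci_s[, 1]
    out$sqrt_selectivity_high <- ci_s[, 2]
    out$mv_covariance_low <- ci_c[, 1]
    out$mv_covariance_high <- ci_c[, 2]
  }
  structure(out, class = c("pls_pattern", class(out)), construct = construct)
}
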