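#' Fit a PLS path model by two-stage estimation
#'
#' Stage 1 builds a standardised score for every construct.  For a
#' [composite()] block the score is a higher-order composite: `k` supervised
#' PLS components are extracted from the standardised indicator block against
#' the model's ultimate outcome (the unique sink construct downstream of the
#' block), and the higher-order score is the regression-weighted combination
#' of those component scores, re-standardised.  Single-indicator constructs
#' are the standardised indicator itself, and interaction constructs the
#' re-standardised product of their parents' scores.  Stage 2 estimates every
#' structural path by ordinary least squares of each endogenous construct's
#' score on its predecessors' scores, all standardised, so path coefficients
#' read as standardised regression coefficients.
#'
#' Construct orientation: a composite score is oriented so that it correlates
#' non-negatively with its stage-1 target (this happens automatically for a
#' regression-weighted composite).
#'
#' @param data A data frame containing every indicator column (complete
#'   cases are used; incomplete rows are dropped with a message).
#' @param model A [pls_model()] specification.
#' @return An object of class `pls_sem`: a list with `scores` (tibble of
#'   standardised construct scores), `weights` (indicator weights of each
#'   composite, scaled so the composite has unit variance), `paths`
#'   (structural coefficients), `r2` (per endogenous construct), `stage1`
#'   details, `model` and `n`.
#' @export
fit_pls <- function(data, model) {
  stopifnot(inherits(model, "pls_model_spec"))
  data <- as.data.frame(data)
  indicators <- unique(unlist(map(model$constructs, "indicators")))
  missing_cols <- setdiff(indicators, names(data))
  if (length(missing_cols)) {
    abort(paste0("Data lacks indicator column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cc <- stats::complete.cases(data[indicators])
  if (!all(cc)) {
    inform(sprintf("Dropping %d incomplete row(s).", sum(!cc)))
    data <- data[cc, , drop = FALSE]
  }
  n <- nrow(data)
  if (n < 3L) abort("Need at least 3 complete observations.")

  scores <- matrix(NA_real_, n, length(model$constructs),
                   dimnames = list(NULL, names(model$constructs)))
  stage1 <- list()
  weights_tbl <- list()

  for (nm in names(model$constructs)) {
    con <- model$constructs[[nm]]
    if (con$type == "single") {
      scores[, nm] <- zscore(data[[con$indicators]], con$indicators)
    } else {
      target <- model_sink(model, nm)
      tcon <- model$constructs[[target]]
      if (is.null(tcon) || tcon$type != "single") {
        abort(sprintf(
          "Stage-1 target `%s` of composite `%s` must be a single-indicator construct.",
          target, nm
        ))
      }
      y <- zscore(data[[tcon$indicators]], tcon$indicators)
      std <- standardize_columns(data[con$indicators])
      comp <- pls_components(std$x, y, k = con$k)
      gamma <- drop(solve(crossprod(comp$scores), crossprod(comp$scores, y)))
      raw <- drop(comp$scores %*% gamma)
      if (sd(raw) < 1e-12) {
        warn(sprintf("Composite `%s` is degenerate; using first component.", nm))
        raw <- comp$scores[, 1]
      }
      scores[, nm] <- (raw - mean(raw)) / sd(raw)
      v <- drop(comp$projection %*% gamma)          # standardised-indicator weights
      v <- v / sd(drop(std$x %*% v))
      stage1[[nm]] <- list(
        target = target, k = con$k, component_scores = comp$scores,
        component_weights = comp$weights, gamma = gamma,
        projection = comp$projection, kept = colnames(std$x),
        dropped = std$dropped, degenerate = comp$degenerate
      )
      weights_tbl[[nm]] <- tibble(construct = nm, indicator = colnames(std$x),
                                  weight = v)
    }
  }

  if (!is.null(model$interactions)) {
    for (i in seq_len(nrow(model$interactions))) {
      it <- model$interactions[i, ]
      prod_score <- scores[, it$a] * scores[, it$b]
      if (sd(prod_score) < 1e-12) {
        abort(sprintf("Interaction `%s` is constant.", it$name))
      }
      scores <- cbind(scores, zscore(prod_score, it$name))
      colnames(scores)[ncol(scores)] <- it$name
    }
  }

  all_edges <- model$paths
  if (!is.null(model$interactions)) {
    all_edges <- bind_rows(all_edges, tibble(from = model$interactions$name,
                                             to = model$interactions$to))
  }
  endo <- unique(all_edges$to)
  paths <- all_edges |> mutate(estimate = NA_real_)
  r2 <- tibble(construct = endo, r2 = NA_real_)
  for (v in endo) {
    parents <- all_edges$from[all_edges$to == v]
    Z <- cbind(`(Intercept)` = 1, scores[, parents, drop = FALSE])
    yv <- scores[, v]
    ft <- lm.fit(Z, yv)
    if (anyNA(ft$coefficients)) {
      abort(sprintf("Collinear predictors of `%s`: %s", v,
                    paste(parents[is.na(ft$coefficients[-1])], collapse = ", ")))
    }
    beta <- ft$coefficients[-1]
    paths$estimate[match(paste(parents, v), paste(paths$from, paths$to))] <- beta
    r2$r2[r2$construct == v] <- 1 - sum(ft$residuals^2) / sum((yv - mean(yv))^2)
  }

  score_tbl <- as_tibble(as.data.frame(scores))
  if ("subject_id" %in% names(data)) {
    score_tbl <- bind_cols(tibble(subject_id = data$subject_id), score_tbl)
  }
  structure(
    list(model = model, n = n, scores = score_tbl,
         weights = if (length(weights_tbl)) list_rbind(weights_tbl) else
           tibble(construct = character(), indicator = character(),
                  weight = numeric()),
         paths = paths, r2 = r2, stage1 = stage1),
    class = "pls_sem"
  )
}

#' @export
print.pls_sem <- function(x, ...) {
  cat(sprintf("PLS path model fit (n = %d)\n", x$n))
  print(as.data.frame(x$paths), row.names = FALSE)
  cat("R-squared:\n")
  print(as.data.frame(x$r2), row.names = FALSE)
  if (!is.null(x$boot)) {
    cat(sprintf("Bootstrap: B = %d (%d failed), %.0f%% percentile CIs\n",
                x$boot$B, x$boot$n_fail, 100 * x$boot$conf))
  }
  invisible(x)
}

#' Tidy the structural coefficients of a PLS path model fit
#'
#' @param x A `pls_sem` fit.
#' @param ... Unused.
#' @return A tibble with `term` (`"from -> to"`), `from`, `to`, `estimate`,
#'   and percentile `conf.low` / `conf.high` when the fit carries bootstrap
#'   replicates.
#' @export
tidy.pls_sem <- function(x, ...) {
  out <- x$paths |>
    mutate(term = paste(.data$from, "->", .data$to), .before = 1)
  if (!is.null(x$boot)) {
    ci <- boot_ci(x$boot$paths, x$boot$conf)
    out$conf.low <- ci[, 1]
    out$conf.high <- ci[, 2]
  }
  out
}

#' One-row summary of a PLS path model fit
#'
#' @param x A `pls_sem` fit.
#' @param ... Unused.
#' @return A tibble with `n`, `n_paths`, bootstrap size `B` (NA when not
#'   bootstrapped) and one `r2_<construct>` column per endogenous construct.
#' @export
glance.pls_sem <- function(x, ...) {
  r2 <- setNames(as.list(x$r2$r2), paste0("r2_", x$r2$construct))
  bind_cols(
    tibble(n = x$n, n_paths = nrow(x$paths),
           B = if (is.null(x$boot)) NA_integer_ else x$boot$B),
    as_tibble(r2)
  )
}

boot_ci <- function(mat, conf) {
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  ci <- t(apply(mat, 2, quantile, probs = probs, na.rm = TRUE, names = FALSE))
  dimnames(ci) <- NULL
  ci
}
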