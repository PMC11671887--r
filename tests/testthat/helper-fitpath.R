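# Build a 1-s epoch series from a vector of minute-level magnitudes (mg).
# Starts at local midnight so calendar days are clean.
make_epochs <- function(minute_mg, subject_id = "s1",
                        start = as.POSIXct("2020-01-06 00:00:00", tz = "UTC")) {
  value <- rep(minute_mg, each = 60)
  time <- start + seq_along(value) - 1
  tibble::tibble(
    subject_id = subject_id, time = time,
    day = as.Date(time, tz = "UTC"), value_mg = value
  )
}

# A day plan: `wear_min` minutes at `level` mg surrounded by zeros to a full
# 1440-min day (zeros first so they form one long non-wear block).
day_minutes <- function(wear_min, level = 30) {
  c(rep(0, 1440 - wear_min), rep(level, wear_min))
}

# Joined analysis table for a simulated cohort.
cohort_data <- function(sim) {
  suppressMessages(
    sim$spectrum |>
      dplyr::inner_join(sim$panel, by = "subject_id") |>
      dplyr::inner_join(fitpath::composite_score(sim$panel), by = "subject_id")
  )
}

# Standardise columns of a matrix (test-side copy, sample SD).
zstd <- function(X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), "/")
}

# Brute-force OLS via normal equations (independent of the fitting path).
ols_oracle <- function(y, Z) {
  Z1 <- cbind(1, Z)
  drop(solve(t(Z1) %*% Z1, t(Z1) %*% y))[-1]
}
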