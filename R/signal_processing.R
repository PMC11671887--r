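#' Zero-phase band-pass filter for raw tri-axial acceleration
#'
#' Removes the gravitational (DC) component and high-frequency noise from each
#' acceleration axis with a Butterworth band-pass applied forward and backward
#' (zero phase, no lag distortion).  The default 0.29--4 Hz band retains the
#' frequency content of human locomotion while suppressing gravity and
#' vibration artefacts.
#'
#' The `order` argument is the order of the underlying band-pass design
#' (default 4, i.e. a 2nd-order low-pass prototype); the forward--backward
#' application squares the magnitude response, so the effective attenuation is
#' twice that of a single pass and the gain at the corner frequencies is 0.5
#' rather than \eqn{1/\sqrt{2}}.
#'
#' @param data A tibble with numeric columns `x`, `y`, `z` in g.  A
#'   `subject_id` column, if present, is respected: each subject's recording
#'   is filtered separately.
#' @param sample_rate Sampling frequency in Hz (constant within a recording).
#' @param low,high Band corner frequencies in Hz; must satisfy
#'   `0 < low < high < sample_rate / 2`.
#' @param order Even band-pass filter order (>= 2).
#' @return The input tibble with `x`, `y`, `z` replaced by their filtered
#'   values; all other columns untouched.
#' @examples
#' t <- seq(0, 10, by = 1 / 30)
#' rec <- tibble::tibble(x = sin(2 * pi * 1.5 * t), y = 0, z = 0.98)
#' flt <- accel_bandpass(rec, sample_rate = 30)
#' @export
accel_bandpass <- function(data, sample_rate, low = 0.29, high = 4, order = 4) {
  stopifnot(is.data.frame(data), all(c("x", "y", "z") %in% names(data)))
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    abort("`sample_rate` must be a single positive number (Hz).")
  }
  if (!(low > 0 && low < high)) {
    abort("Corner frequencies must satisfy 0 < low < high.")
  }
  if (high >= sample_rate / 2) {
    abort(sprintf(
      "Upper corner (%g Hz) must be below the Nyquist frequency (%g Hz).",
      high, sample_rate / 2
    ))
  }
  if (order < 2 || order %% 2 != 0) {
    abort("`order` must be an even integer >= 2.")
  }
  flt <- bandpass_design(sample_rate, low, high, order)
  apply_axes <- function(df) {
    if (anyNA(df[c("x", "y", "z")]) ||
        !all(is.finite(df$x), is.finite(df$y), is.finite(df$z))) {
      abort("Acceleration axes must be finite and non-missing.")
    }
    df$x <- as.numeric(signal::filtfilt(flt, df$x))
    df$y <- as.numeric(signal::filtfilt(flt, df$y))
    df$z <- as.numeric(signal::filtfilt(flt, df$z))
    df
  }
  if ("subject_id" %in% names(data)) {
    data |>
      group_by(.data$subject_id) |>
      group_modify(~ apply_axes(.x)) |>
      ungroup()
  } else {
    as_tibble(apply_axes(data))
  }
}

# Butterworth band-pass of total order `order` (signal::butter takes the
# prototype order, i.e. order/2 for a band-pass).
bandpass_design <- function(sample_rate, low, high, order = 4) {
  signal::butter(order / 2, c(low, high) / (sample_rate / 2), type = "pass")
}

#' Magnitude (and phase-free power gain) of the band-pass at given frequencies
#'
#' Evaluates the designed filter's frequency response analytically.  Because
#' the filter is applied forward and backward, the amplitude gain of the whole
#' filtering operation is `|H(f)|^2`; that squared magnitude is what this
#' function returns.  Used both as a design diagnostic and by
#' [simulate_recording()] to back-compute sinusoid amplitudes that land at a
#' prescribed post-filter epoch magnitude.
#'
#' @param freq Frequencies in Hz at which to evaluate the response.
#' @inheritParams accel_bandpass
#' @return Numeric vector of zero-phase amplitude gains, one per frequency.
#' @export
bandpass_gain <- function(freq, sample_rate, low = 0.29, high = 4, order = 4) {
  flt <- bandpass_design(sample_rate, low, high, order)
  vapply(freq, function(f) {
    z <- exp(-1i * 2 * pi * f / sample_rate)
    h <- sum(flt$b * z^(seq_along(flt$b) - 1)) /
      sum(flt$a * z^(seq_along(flt$a) - 1))
    Mod(h)^2
  }, numeric(1))
}

#' Euclidean vector magnitude of the three acceleration axes
#'
#' @param data A tibble with numeric columns `x`, `y`, `z` (g).
#' @return The tibble with an added `vm` column, `sqrt(x^2 + y^2 + z^2)`, in g.
#' @export
accel_magnitude <- function(data) {
  stopifnot(all(c("x", "y", "z") %in% names(data)))
  mutate(as_tibble(data), vm = sqrt(.data$x^2 + .data$y^2 + .data$z^2))
}

#' Aggregate sample-level magnitudes into fixed epochs
#'
#' Averages the vector magnitude over consecutive windows of `epoch_length`
#' seconds and converts to milli-g.  A trailing window with fewer than
#' `sample_rate * epoch_length` samples is dropped.
#'
#' @param data A tibble with a `vm` column (g) and optionally `time`
#'   (POSIXct) and `subject_id` columns.
#' @param sample_rate Sampling frequency in Hz.
#' @param epoch_length Epoch duration in seconds (default 1).
#' @return A tibble with one row per epoch: `subject_id` (if supplied),
#'   `time` (epoch start), `day` (calendar date, local midnight boundary) and
#'   `value_mg` (mean magnitude in milli-g).
#' @export
accel_epochs <- function(data, sample_rate, epoch_length = 1) {
  stopifnot("vm" %in% names(data))
  spe <- sample_rate * epoch_length
  if (spe < 1) abort("`epoch_length * sample_rate` must be at least 1 sample.")
  spe <- as.integer(round(spe))
  one <- function(df) {
    n <- nrow(df)
    if (n == 0L) abort("Empty magnitude series.")
    n_epochs <- n %/% spe
    if (n_epochs == 0L) abort("Recording shorter than one epoch.")
    vm <- df$vm[seq_len(n_epochs * spe)]
    value_mg <- colMeans(matrix(vm, nrow = spe)) * 1000
    idx <- seq(1L, by = spe, length.out = n_epochs)
    out <- tibble(value_mg = value_mg)
    if ("time" %in% names(df)) {
      out$time <- df$time[idx]
      out$day <- as.Date(out$time, tz = tz_of(out$time))
      out <- out[c("time", "day", "value_mg")]
    }
    out
  }
  if ("subject_id" %in% names(data)) {
    as_tibble(data) |>
      group_by(.data$subject_id) |>
      group_modify(~ one(.x)) |>
      ungroup()
  } else {
    one(as_tibble(data))
  }
}

tz_of <- function(x) {
  tz <- attr(x, "tzone")
  if (is.null(tz) || !nzchar(tz[1])) "UTC" else tz[1]
}

#' Flag non-wear time in an epoch series
#'
#' Non-wear is a maximal run of at least `window` minutes of zero output,
#' where interruptions totalling at most `allowance` minutes with output below
#' the sedentary threshold do not break the run.  The rule is evaluated on
#' 1-minute means of the epoch magnitudes, since it is stated in minutes;
#' "zero output" is a minute mean below `zero_tolerance` (filtered real
#' signals are never exactly zero).  Runs must begin and end on a zero minute.
#'
#' @param data Epoch tibble from [accel_epochs()] (contiguous in time per
#'   subject).
#' @param window Minimum non-wear run length in minutes (default 60).
#' @param allowance Maximum total interruption in minutes (default 2); must be
#'   smaller than `window`.
#' @param sedentary_threshold Upper bound (mg) for an interruption minute
#'   (default 25 mg, the lowest spectrum edge above zero activity).
#' @param zero_tolerance Minute-mean magnitude (mg) below which output counts
#'   as zero (default 1 mg).
#' @param epoch_length Epoch duration in seconds (default 1).
#' @return The input tibble with a logical `wear` column.  Re-running the
#'   detector on its own output changes nothing.
#' @export
detect_nonwear <- function(data, window = 60, allowance = 2,
                           sedentary_threshold = 25, zero_tolerance = 1,
                           epoch_length = 1) {
  stopifnot("value_mg" %in% names(data))
  if (allowance >= window) abort("`allowance` must be smaller than `window`.")
  epm <- as.integer(round(60 / epoch_length))
  one <- function(df) {
    n <- nrow(df)
    n_min <- n %/% epm
    wear <- rep(TRUE, n)
    if (n_min >= window) {
      v <- df$value_mg[seq_len(n_min * epm)]
      minute_mean <- colMeans(matrix(v, nrow = epm))
      nw_min <- nonwear_minutes(minute_mean, window, allowance,
                                sedentary_threshold, zero_tolerance)
      wear[seq_len(n_min * epm)] <- rep(!nw_min, each = epm)
    }
    df$wear <- wear
    df
  }
  if ("subject_id" %in% names(data)) {
    as_tibble(data) |>
      group_by(.data$subject_id) |>
      group_modify(~ one(.x)) |>
      ungroup()
  } else {
    one(as_tibble(data))
  }
}

# Core minute-level rule.  Within each maximal run of minutes below the
# sedentary threshold, every stretch that starts and ends on a zero minute,
# contains at most `allowance` sub-threshold (non-zero) minutes and spans at
# least `window` minutes is flagged.  Vectorised two-pointer scan.
nonwear_minutes <- function(minute_mean, window, allowance,
                            sedentary_threshold, zero_tolerance) {
  L <- length(minute_mean)
  flag <- rep(FALSE, L)
  below <- minute_mean < sedentary_threshold
  zero <- minute_mean < zero_tolerance
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (b in which(r$values & r$lengths >= window)) {
    i0 <- starts[b]; i1 <- ends[b]
    z <- zero[i0:i1]
    lb <- !z                      # interruption minutes within the block
    Lb <- i1 - i0 + 1L
    zpos <- which(z)
    if (!length(zpos)) next
    lowcum <- cumsum(lb)
    lowpos <- which(lb)
    # furthest index whose interruption count stays within the allowance
    k <- lowcum[zpos] - as.integer(lb[zpos]) + allowance + 1L
    e_bound <- ifelse(k <= length(lowpos), lowpos[k] - 1L, Lb)
    # trim the end back to the last zero minute
    prev_zero <- cummax(ifelse(z, seq_len(Lb), 0L))
    e <- prev_zero[pmax(e_bound, 1L)]
    len <- e - zpos + 1L
    ok <- len >= window
    if (any(ok)) {
      # difference-array union of the flagged intervals (indices may repeat)
      cover <- tabulate(zpos[ok], Lb + 1L) - tabulate(e[ok] + 1L, Lb + 1L)
      flag[i0:i1] <- flag[i0:i1] | (cumsum(cover[seq_len(Lb)]) > 0L)
    }
  }
  flag
}

#' Standard intensity-spectrum bin edges
#'
#' Lower edges of the 22 intensity bins: 0, 25, 50, then 100 mg rising by
#' 50 mg to 1000 mg; everything at or above 1000 mg is collapsed into a
#' single top bin (data become too sparse above that intensity).
#'
#' @return Numeric vector of 22 lower bin edges in mg.
#' @export
spectrum_edges <- function() c(0, 25, 50, seq(100, 1000, by = 50))

#' Column names for the spectrum bins implied by a set of edges
#' @param edges Lower bin edges in mg (default [spectrum_edges()]).
#' @return Character vector, one name per bin, e.g. `"bin_25_50"`,
#'   ending in `"bin_<top>_plus"`.
#' @export
spectrum_bin_names <- function(edges = spectrum_edges()) {
  n <- length(edges)
  c(sprintf("bin_%g_%g", edges[-n], edges[-1]), sprintf("bin_%g_plus", edges[n]))
}

# Shared day-level machinery: classify wear epochs with `breaks`, count
# minutes per class and non-wear minutes per calendar day, keep valid days,
# average per person.
daily_class_summary <- function(data, breaks, labels, min_wear_hours,
                                min_valid_days, epoch_length) {
  stopifnot(all(c("value_mg", "wear", "day") %in% names(data)))
  min_per_epoch <- epoch_length / 60
  one <- function(df) {
    days <- df |>
      group_by(.data$day) |>
      summarise(
        wear_min = sum(.data$wear) * min_per_epoch,
        nonwear = sum(!.data$wear) * min_per_epoch,
        counts = list(as.vector(table(cut(
          .data$value_mg[.data$wear],
          breaks = breaks, labels = labels, right = FALSE
        )))),
        .groups = "drop"
      ) |>
      mutate(valid_day = .data$wear_min >= min_wear_hours * 60)
    vd <- days[days$valid_day, , drop = FALSE]
    n_valid <- nrow(vd)
    if (n_valid > 0) {
      mat <- do.call(rbind, vd$counts) * min_per_epoch
      mins <- colMeans(mat)
      nonwear <- mean(vd$nonwear)
    } else {
      mins <- rep(NA_real_, length(labels))
      nonwear <- NA_real_
    }
    out <- as_tibble(as.list(setNames(mins, labels)))
    out$nonwear <- nonwear
    out$n_valid_days <- n_valid
    out$valid <- n_valid >= min_valid_days
    out
  }
  if ("subject_id" %in% names(data)) {
    as_tibble(data) |>
      group_by(.data$subject_id) |>
      group_modify(~ one(.x)) |>
      ungroup()
  } else {
    one(as_tibble(data))
  }
}

#' Per-person intensity spectrum averaged over valid days
#'
#' For each calendar day with at least `min_wear_hours` of wear, wear epochs
#' are binned by magnitude into the intensity-spectrum bins and non-wear
#' minutes are counted; per-person values are the means over valid days.  A
#' person's measurement is valid when it contains at least `min_valid_days`
#' valid days; invalid persons are carried through with `valid = FALSE` (and
#' `NA` bin values when no day is valid) so the exclusion is explicit
#' downstream.
#'
#' @param data Wear-flagged epoch tibble from [detect_nonwear()].
#' @param edges Lower bin edges in mg; the top bin is open-ended.
#' @param min_wear_hours Minimum wear time for a valid day (hours).
#' @param min_valid_days Minimum number of valid days for a valid measurement.
#' @param epoch_length Epoch duration in seconds.
#' @return One row per subject: bin minutes per day (columns named by
#'   [spectrum_bin_names()]), `nonwear` min/day, `n_valid_days`, `valid`.
#'   On complete 24-h days the bin columns and `nonwear` sum to 1440.
#' @export
summarize_days <- function(data, edges = spectrum_edges(), min_wear_hours = 10,
                           min_valid_days = 4, epoch_length = 1) {
  stopifnot(is.numeric(edges), !is.unsorted(edges, strictly = TRUE))
  daily_class_summary(
    data,
    breaks = c(edges, Inf), labels = spectrum_bin_names(edges),
    min_wear_hours = min_wear_hours, min_valid_days = min_valid_days,
    epoch_length = epoch_length
  )
}

#' Crude intensity cut-points
#'
#' Boundaries (mg) between the five coarse intensity classes used for
#' reference summaries.  The defaults coincide with spectrum edges so that
#' class totals partition exactly into sums of spectrum bins; calibrated
#' values from a specific device study can be substituted.
#'
#' @param sedentary,moderate,vigorous,very_vigorous Upper bounds (mg) of the
#'   sedentary, light, moderate and vigorous classes respectively; must be
#'   strictly increasing.
#' @return A named numeric vector of class `fitpath_cutpoints`.
#' @export
cutpoint_config <- function(sedentary = 50, moderate = 150, vigorous = 500,
                            very_vigorous = 1000) {
  cp <- c(sedentary = sedentary, moderate = moderate, vigorous = vigorous,
          very_vigorous = very_vigorous)
  if (is.unsorted(cp, strictly = TRUE) || any(cp <= 0)) {
    abort("Cut-points must be positive and strictly increasing.")
  }
  structure(cp, class = "fitpath_cutpoints")
}

#' Minutes per day in the five coarse intensity classes
#'
#' Applies the same valid-day averaging as [summarize_days()] but with the
#' coarse sedentary / light / moderate / vigorous / very-vigorous classes.
#'
#' @inheritParams summarize_days
#' @param cutpoints Boundaries from [cutpoint_config()].
#' @return One row per subject: `sed`, `lpa`, `mpa`, `vpa`, `vvpa` min/day,
#'   plus `nonwear`, `n_valid_days` and `valid`.
#' @export
cutpoint_summary <- function(data, cutpoints = cutpoint_config(),
                             min_wear_hours = 10, min_valid_days = 4,
                             epoch_length = 1) {
  daily_class_summary(
    data,
    breaks = c(0, unclass(cutpoints), Inf),
    labels = c("sed", "lpa", "mpa", "vpa", "vvpa"),
    min_wear_hours = min_wear_hours, min_valid_days = min_valid_days,
    epoch_length = epoch_length
  )
}

#' Read a raw recording from CSV
#'
#' Expects columns `timestamp,x,y,z` (axes in g).  If `timestamp` is absent,
#' times are reconstructed from `start_time` and the sample rate.
#'
#' @param path CSV file path.
#' @param subject_id Subject label attached to every row.
#' @param sample_rate Sampling frequency in Hz (used when reconstructing
#'   timestamps; stored nowhere in the file).
#' @param start_time POSIXct start used when the file has no timestamp column.
#' @return A raw-recording tibble (`subject_id`, `time`, `x`, `y`, `z`).
#' @export
read_recording <- function(path, subject_id, sample_rate,
                           start_time = as.POSIXct("2020-01-06", tz = "UTC")) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("x", "y", "z") %in% names(raw))) {
    abort(sprintf("Recording %s lacks x/y/z columns.", path))
  }
  if (nrow(raw) == 0L) abort(sprintf("Recording %s is empty.", path))
  if ("timestamp" %in% names(raw)) {
    time <- as.POSIXct(raw$timestamp, tz = "UTC")
  } else {
    time <- start_time + (seq_len(nrow(raw)) - 1) / sample_rate
  }
  tibble(subject_id = subject_id, time = time,
         x = raw$x, y = raw$y, z = raw$z)
}

#' One-call processing of a raw recording into spectrum and cut-point rows
#'
#' Chains [accel_bandpass()], [accel_magnitude()], [accel_epochs()],
#' [detect_nonwear()], [summarize_days()] and [cutpoint_summary()].
#'
#' @param data Raw recording tibble (`time`, `x`, `y`, `z`, optional
#'   `subject_id`).
#' @param sample_rate Sampling frequency in Hz.
#' @param config Processing parameters from [signal_config()].
#' @return List with elements `epochs`, `spectrum`, `cutpoints`.
#' @export
process_recording <- function(data, sample_rate, config = signal_config()) {
  epochs <- data |>
    accel_bandpass(sample_rate, config$filter_low, config$filter_high,
                   config$filter_order) |>
    accel_magnitude() |>
    accel_epochs(sample_rate, config$epoch_length) |>
    detect_nonwear(config$nonwear_window, config$nonwear_allowance,
                   config$sedentary_threshold, config$zero_tolerance,
                   config$epoch_length)
  list(
    epochs = epochs,
    spectrum = summarize_days(epochs, config$edges, config$min_wear_hours,
                              config$min_valid_days, config$epoch_length),
    cutpoints = cutpoint_summary(epochs, config$cutpoints,
                                 config$min_wear_hours, config$min_valid_days,
                                 config$epoch_length)
  )
}

#' Signal-processing parameter bundle
#'
#' @param filter_low,filter_high Band corners in Hz.
#' @param filter_order Even Butterworth band-pass order.
#' @param epoch_length Epoch duration in seconds.
#' @param nonwear_window,nonwear_allowance Non-wear rule parameters (minutes).
#' @param sedentary_threshold,zero_tolerance Non-wear magnitude thresholds (mg).
#' @param min_wear_hours,min_valid_days Valid-day / valid-measurement rules.
#' @param edges Spectrum bin edges (mg).
#' @param cutpoints Coarse class boundaries from [cutpoint_config()].
#' @return A named list of parameters.
#' @export
signal_config <- function(filter_low = 0.29, filter_high = 4, filter_order = 4,
                          epoch_length = 1, nonwear_window = 60,
                          nonwear_allowance = 2, sedentary_threshold = 25,
                          zero_tolerance = 1, min_wear_hours = 10,
                          min_valid_days = 4, edges = spectrum_edges(),
                          cutpoints = cutpoint_config()) {
  list(
    filter_low = filter_low, filter_high = filter_high,
    filter_order = filter_order, epoch_length = epoch_length,
    nonwear_window = nonwear_window, nonwear_allowance = nonwear_allowance,
    sedentary_threshold = sedentary_threshold, zero_tolerance = zero_tolerance,
    min_wear_hours = min_wear_hours, min_valid_days = min_valid_days,
    edges = edges, cutpoints = cutpoints
  )
}
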