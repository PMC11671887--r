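test_that("band-pass keeps locomotor frequencies and removes gravity and noise", {
  fs <- 30
  t <- seq(0, 120, by = 1 / fs)
  amp <- 0.2
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))

  measured_gain <- function(f) {
    rec <- tibble::tibble(x = amp * sin(2 * pi * f * t), y = 0, z = 0)
    out <- accel_bandpass(rec, fs)
    max(abs(out$x[mid])) / amp
  }

  # passband: 1 Hz comes through essentially unattenuated
  g1 <- measured_gain(1)
  expect_lt(abs(g1 - 1), 0.05)
  # the empirical gain agrees with the analytic frequency-response oracle
  expect_lt(abs(g1 - bandpass_gain(1, fs)), 0.02)
  # stopband: 10 Hz is crushed
  g10 <- measured_gain(10)
  expect_lt(g10, 0.10)
  expect_lt(abs(g10 - bandpass_gain(10, fs)), 0.02)

  # constant (gravity) input is removed entirely
  rec <- tibble::tibble(x = rep(0.5, length(t)), y = rep(0, length(t)),
                        z = rep(1, length(t)))
  out <- accel_bandpass(rec, fs)
  expect_lt(max(abs(out$z[mid])), 1e-6)

  # linearity: filtering a scaled signal scales the output
  rec1 <- tibble::tibble(x = sin(2 * pi * 1.3 * t) + 0.3 * sin(2 * pi * 3 * t),
                         y = 0, z = 0)
  rec3 <- dplyr::mutate(rec1, x = 3 * x)
  expect_equal(accel_bandpass(rec3, fs)$x, 3 * accel_bandpass(rec1, fs)$x,
               tolerance = 1e-10)

  # corner validation
  expect_error(accel_bandpass(rec1, fs, low = 0.29, high = 16), "Nyquist")
  expect_error(accel_bandpass(rec1, fs, low = 5, high = 4))
})

test_that("vector magnitude is the per-sample Euclidean norm", {
  rec <- tibble::tibble(x = c(3, 0, -2, 0.3), y = c(4, 0, 0, -0.4),
                        z = c(0, 0, 0, 1.2))
  vm <- accel_magnitude(rec)$vm
  expect_equal(vm, c(5, 0, 2, sqrt(0.3^2 + 0.4^2 + 1.2^2)))
})

test_that("epoch aggregation averages within whole epochs and drops remainders", {
  # constant 0.05 g over one second of 30 Hz samples -> a single 50 mg epoch
  e1 <- accel_epochs(tibble::tibble(vm = rep(0.05, 30)), 30)
  expect_equal(e1$value_mg, 50)

  # alternating 0 / 0.1 g -> two epochs of 50 mg
  e2 <- accel_epochs(tibble::tibble(vm = rep(c(0, 0.1), 30)), 30)
  expect_equal(e2$value_mg, c(50, 50))

  # trailing partial epoch dropped
  e3 <- accel_epochs(tibble::tibble(vm = rep(0.05, 45)), 30)
  expect_equal(nrow(e3), 1L)

  expect_error(accel_epochs(tibble::tibble(vm = numeric(0)), 30), "Empty")
})

test_that("non-wear rule reproduces hand-counted minutes on constructed days", {
  act <- rep(100, 30)  # half an hour of clear activity

  # 70 min of zeros bounded by activity -> exactly those 70 min flagged
  e <- make_epochs(c(act, rep(0, 70), act))
  w <- detect_nonwear(e)
  expect_equal(sum(!w$wear) / 60, 70)
  expect_true(all(!w$wear[(30 * 60 + 1):(100 * 60)]))

  # 59 min of zeros: below the window, nothing flagged
  e <- make_epochs(c(act, rep(0, 59), act))
  expect_equal(sum(!detect_nonwear(e)$wear), 0)

  # 30 zeros + 2 min below the sedentary threshold + 30 zeros -> all 62 min
  e <- make_epochs(c(act, rep(0, 30), rep(10, 2), rep(0, 30), act))
  expect_equal(sum(!detect_nonwear(e)$wear) / 60, 62)

  # a 3-min interruption exceeds the allowance and splits the run
  e <- make_epochs(c(act, rep(0, 30), rep(10, 3), rep(0, 30), act))
  expect_equal(sum(!detect_nonwear(e)$wear), 0)

  # an interruption at or above the sedentary threshold always breaks the run
  e <- make_epochs(c(act, rep(0, 59), rep(30, 1), rep(0, 59), act))
  expect_equal(sum(!detect_nonwear(e)$wear), 0)

  expect_error(detect_nonwear(make_epochs(act), allowance = 60), "allowance")
})

test_that("re-running non-wear detection on flagged output changes nothing", {
  minutes <- c(rep(100, 45), rep(0, 75), rep(20, 5), rep(80, 200), rep(0, 400))
  e1 <- detect_nonwear(make_epochs(minutes))
  e2 <- detect_nonwear(e1)
  expect_identical(e1$wear, e2$wear)
})

test_that("day summaries apply the valid-day and valid-measurement rules", {
  # one 24-h day: 14 h non-wear zeros then 10 h wear at 30 mg
  e <- detect_nonwear(make_epochs(day_minutes(600, 30)))
  sp <- summarize_days(e)
  expect_true(sp$n_valid_days == 1 && !sp$valid)   # 1 day < 4-day rule
  expect_equal(sp$bin_25_50, 600)
  expect_equal(sp$nonwear, 840)
  # per-day closure: bins + non-wear account for the full 1440 min
  expect_equal(sum(sp[1, spectrum_bin_names()]) + sp$nonwear, 1440,
               tolerance = 1e-6)

  # 9.5 h of wear -> that day is invalid
  e2 <- detect_nonwear(make_epochs(day_minutes(570, 30)))
  sp2 <- summarize_days(e2)
  expect_equal(sp2$n_valid_days, 0L)

  # exactly 10 h of wear counts (boundary)
  expect_equal(summarize_days(e)$n_valid_days, 1L)

  # 4 valid days -> valid measurement; 3 -> not
  four <- detect_nonwear(make_epochs(rep(day_minutes(610, 30), 4)))
  expect_true(summarize_days(four)$valid)
  expect_false(summarize_days(four, min_valid_days = 5)$valid)
  three <- detect_nonwear(make_epochs(rep(day_minutes(610, 30), 3)))
  expect_false(summarize_days(three)$valid)

  # raising the wear requirement never increases the number of valid days
  mixed <- detect_nonwear(make_epochs(c(
    day_minutes(610, 30), day_minutes(700, 40), day_minutes(590, 30)
  )))
  hrs <- c(8, 10, 11, 12)
  nvd <- sapply(hrs, function(h) summarize_days(mixed, min_wear_hours = h)$n_valid_days)
  expect_true(all(diff(nvd) <= 0))
})

test_that("cut-point classes partition consistently with the spectrum bins", {
  minutes <- c(rep(0, 700), rep(10, 300), rep(70, 120), rep(200, 180),
               rep(320, 60), rep(620, 50), rep(1500, 30))
  e <- detect_nonwear(make_epochs(minutes))
  sp <- summarize_days(e)
  cp <- cutpoint_summary(e)  # default cut-points sit on spectrum edges

  bn <- spectrum_bin_names()
  expect_equal(cp$sed, sum(sp[1, bn[1:2]]))     # < 50 mg
  expect_equal(cp$lpa, sum(sp[1, bn[3:4]]))     # [50, 150)
  expect_equal(cp$mpa, sum(sp[1, bn[5:11]]))    # [150, 500)
  expect_equal(cp$vpa, sum(sp[1, bn[12:21]]))   # [500, 1000)
  expect_equal(cp$vvpa, sp[[1, bn[22]]])        # >= 1000

  # brute-force count oracle on the wear minutes of the constructed day
  wear_lv <- minutes[minutes >= 10]  # the 700 zero-minutes are one non-wear run
  expect_equal(cp$sed, sum(wear_lv < 50))
  expect_equal(cp$mpa, sum(wear_lv >= 150 & wear_lv < 500))
  expect_equal(cp$vvpa, sum(wear_lv >= 1000))

  # all wear below the sedentary threshold -> everything lands in SED
  e2 <- detect_nonwear(make_epochs(c(rep(0, 720), rep(20, 720))))
  cp2 <- cutpoint_summary(e2)
  expect_equal(cp2$sed, 720)
  expect_equal(cp2$lpa + cp2$mpa + cp2$vpa + cp2$vvpa, 0)

  expect_error(cutpoint_config(sedentary = 100, moderate = 90), "increasing")
})
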