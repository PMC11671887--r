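test_that("the seven model specifications have the stated structure", {
  m1 <- study_model(1)
  expect_length(m1$constructs, 2)
  expect_equal(nrow(m1$paths), 1)
  expect_equal(m1$constructs$PA$k, 2)
  expect_true("nonwear" %in% m1$constructs$PA$indicators)

  m6 <- study_model(6)
  to_crf <- m6$paths$from[m6$paths$to == "CRF"]
  to_cs <- m6$paths$from[m6$paths$to == "CS"]
  expect_setequal(to_crf, c("PA", "sex", "age"))
  expect_setequal(to_cs, c("PA", "CRF", "sex", "age"))

  m7 <- study_model(7)
  expect_equal(nrow(m7$interactions), 1)
  expect_equal(m7$interactions$to, "CS")
  expect_setequal(c(m7$interactions$a, m7$interactions$b), c("sex", "CRF"))

  m5 <- study_model(5)
  expect_false("PA" %in% names(m5$constructs))

  expect_error(study_model(8), "1..7")
})

test_that("mediation arithmetic handles edge cases", {
  e0 <- mediation_effects(a = 0, b = 0.5, c_direct = 0.1)
  est <- setNames(e0$estimate, e0$quantity)
  expect_equal(est[["indirect"]], 0)
  expect_equal(est[["proportion_mediated"]], 0)

  full <- mediation_effects(a = 0.5, b = 0.5, c_direct = 0)
  expect_equal(full$estimate[full$quantity == "proportion_mediated"], 1)

  expect_warning(z <- mediation_effects(a = 0.5, b = -0.4, c_direct = 0.2),
                 "zero")
  expect_true(is.na(z$estimate[z$quantity == "proportion_mediated"]))

  expect_warning(mediation_effects(a = 0.5, b = -0.5, c_direct = 0.3),
                 "opposite signs")
})

test_that("models sharing an outcome share the same activity pattern", {
  sim <- simulate_cohort(n = 400, seed = 31)
  d <- cohort_data(sim)
  f1 <- fit_pls(d, study_model(1))
  f2 <- fit_pls(d, study_model(2))
  # identical stage-1 weights, hence identical PA scores
  expect_equal(f1$weights$weight, f2$weights$weight, tolerance = 1e-12)
  expect_equal(f1$scores$PA, f2$scores$PA, tolerance = 1e-12)
  # model 3 targets CRF instead, so its pattern differs
  f3 <- fit_pls(d, study_model(3))
  expect_gt(max(abs(f1$weights$weight - f3$weights$weight)), 1e-4)
})

test_that("adding covariates never decreases explained variance", {
  sim <- simulate_cohort(n = 500, seed = 32)
  d <- cohort_data(sim)
  r2 <- function(f, con) f$r2$r2[f$r2$construct == con]
  f1 <- fit_pls(d, study_model(1)); f2 <- fit_pls(d, study_model(2))
  expect_gte(r2(f2, "CS"), r2(f1, "CS"))
  f3 <- fit_pls(d, study_model(3)); f4 <- fit_pls(d, study_model(4))
  expect_gte(r2(f4, "CRF"), r2(f3, "CRF"))
})

test_that("run_study produces a coherent, reproducible bundle", {
  sim <- simulate_cohort(n = 250, seed = 41)
  s1 <- suppressMessages(run_study(sim$spectrum, sim$panel, B = 100, seed = 5,
                                   models = c(1, 3, 6)))
  expect_named(s1$fits, c("model_1", "model_3", "model_6"))
  expect_s3_class(s1$mediation, "pls_mediation")
  expect_true(all(c("model_1", "model_6") %in% names(s1$patterns)))
  expect_true(all(s1$fits$model_6$r2$r2 >= 0 & s1$fits$model_6$r2$r2 <= 1))

  # determinism: identical seed, identical summary
  s2 <- suppressMessages(run_study(sim$spectrum, sim$panel, B = 100, seed = 5,
                                   models = c(1, 3, 6)))
  expect_identical(s1$summary, s2$summary)

  # invalid subjects and join mismatches are excluded with messages
  spec_bad <- sim$spectrum
  spec_bad$valid[1:10] <- FALSE
  panel_short <- sim$panel[-(1:5), ]
  expect_message(
    s3 <- run_study(spec_bad, panel_short, B = 100, seed = 5, models = 6),
    "valid measurement"
  )
  # subjects 1-10 are invalid; the missing panel rows are a subset of them
  expect_equal(nrow(s3$data), 240)

  # empty join errors
  panel_none <- dplyr::mutate(sim$panel, subject_id = paste0("x", subject_id))
  expect_error(
    suppressMessages(run_study(sim$spectrum, panel_none, B = 100, models = 1))
  )
})

test_that("the results bundle writes and a serialised model round-trips", {
  sim <- simulate_cohort(n = 200, seed = 43)
  s <- suppressMessages(run_study(sim$spectrum, sim$panel, B = 100, seed = 2,
                                  models = 6))
  dir <- withr::local_tempdir()
  write_study(s, dir)
  expect_true(file.exists(file.path(dir, "model_6", "paths.csv")))
  expect_true(file.exists(file.path(dir, "model_6", "pattern.csv")))
  expect_true(file.exists(file.path(dir, "mediation.json")))
  med <- jsonlite::read_json(file.path(dir, "mediation.json"),
                             simplifyVector = TRUE)
  expect_equal(med$estimate[med$quantity == "indirect"],
               med$estimate[med$quantity == "a"] *
                 med$estimate[med$quantity == "b"],
               tolerance = 1e-12)

  m7 <- study_model(7)
  p_yaml <- file.path(dir, "model.yaml")
  write_model(m7, p_yaml)
  expect_equal(read_model(p_yaml), m7)
  p_json <- file.path(dir, "model.json")
  write_model(m7, p_json)
  expect_equal(read_model(p_json), m7)
})
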