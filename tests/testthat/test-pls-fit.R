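make_latent_data <- function(n = 200, seed = 5) {
  set.seed(seed)
  tibble::tibble(
    crf = rnorm(n),
    sex = rbinom(n, 1, 0.5),
    age = runif(n, 50, 64),
    cs = 0.5 * scale(crf)[, 1] - 0.2 * scale(sex)[, 1] + rnorm(n, 0, 0.8)
  )
}

test_that("a single-predictor model yields the Pearson correlation as its path", {
  d <- make_latent_data()
  m <- pls_model(CRF = "crf", CS = "cs", paths = "CRF -> CS")
  f <- fit_pls(d, m)
  expect_equal(f$paths$estimate, cor(d$crf, d$cs), tolerance = 1e-12)
  expect_equal(f$r2$r2, cor(d$crf, d$cs)^2, tolerance = 1e-12)
})

test_that("structural coefficients equal brute-force OLS on the latent scores", {
  d <- make_latent_data(300, seed = 8)
  m <- pls_model(CRF = "crf", CS = "cs", sex = "sex", age = "age",
                 paths = c("CRF -> CS", "sex -> CS", "age -> CS"))
  f <- fit_pls(d, m)
  Z <- as.matrix(f$scores[c("CRF", "sex", "age")])
  beta <- ols_oracle(f$scores$CS, Z)
  expect_equal(f$paths$estimate, unname(beta), tolerance = 1e-10)

  # the same equivalence holds with a composite block in the model
  sim <- simulate_cohort(n = 500, seed = 13)
  dd <- cohort_data(sim)
  f6 <- fit_pls(dd, study_model(6))
  for (target in c("CRF", "CS")) {
    parents <- f6$paths$from[f6$paths$to == target]
    beta <- ols_oracle(f6$scores[[target]],
                       as.matrix(f6$scores[parents]))
    expect_equal(f6$paths$estimate[f6$paths$to == target], unname(beta),
                 tolerance = 1e-10)
  }
})

test_that("every construct score is standardised", {
  sim <- simulate_cohort(n = 300, seed = 21)
  f <- fit_pls(cohort_data(sim), study_model(6))
  for (nm in c("PA", "CRF", "CS", "sex", "age")) {
    expect_equal(mean(f$scores[[nm]]), 0, tolerance = 1e-8)
    expect_equal(sd(f$scores[[nm]]), 1, tolerance = 1e-8)
  }
})

test_that("with k = 1 the model reduces to single-component PLS regression", {
  set.seed(33)
  n <- 150
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("b", 1:6)
  y <- X %*% rnorm(6, 0, 0.3) + rnorm(n)
  d <- dplyr::bind_cols(tibble::as_tibble(as.data.frame(X)),
                        tibble::tibble(cs = as.numeric(y)))
  m <- pls_model(PA = composite(paste0("b", 1:6), k = 1), CS = "cs",
                 paths = "PA -> CS")
  f <- fit_pls(d, m)
  # one standardised predictor: beta^2 = R^2
  expect_equal(f$paths$estimate^2, f$r2$r2, tolerance = 1e-12)
  # composite weights proportional to the covariance vector X'y (closed form)
  w <- f$weights$weight
  w_oracle <- drop(t(zstd(X)) %*% as.numeric(zstd(y)))
  expect_equal(w / sqrt(sum(w^2)), unname(w_oracle / sqrt(sum(w_oracle^2))),
               tolerance = 1e-10)
})

test_that("sign conventions: indicator flips flip paths, composites stay oriented", {
  d <- make_latent_data(250, seed = 9)
  m <- pls_model(CRF = "crf", CS = "cs", sex = "sex",
                 paths = c("CRF -> CS", "sex -> CS"))
  f <- fit_pls(d, m)
  d2 <- dplyr::mutate(d, crf = -crf)
  f2 <- fit_pls(d2, m)
  expect_equal(f2$scores$CRF, -f$scores$CRF, tolerance = 1e-12)
  expect_equal(f2$paths$estimate[1], -f$paths$estimate[1], tolerance = 1e-12)
  expect_equal(f2$paths$estimate[2], f$paths$estimate[2], tolerance = 1e-12)
  expect_equal(f2$r2$r2, f$r2$r2, tolerance = 1e-12)

  # flipping all indicators of a composite leaves its oriented score intact
  sim <- simulate_cohort(n = 300, seed = 4)
  dd <- cohort_data(sim)
  f1 <- fit_pls(dd, study_model(1))
  dd2 <- dplyr::mutate(dd, dplyr::across(dplyr::all_of(pa_block()), ~ -.x))
  f1b <- fit_pls(dd2, study_model(1))
  expect_equal(f1b$scores$PA, f1$scores$PA, tolerance = 1e-10)
  expect_gte(cor(f1$scores$PA, f1$scores$CS), 0)
})

test_that("degenerate inputs are rejected with informative errors", {
  d <- make_latent_data(100, seed = 2)
  d$crf2 <- d$crf
  m <- pls_model(A = "crf", B = "crf2", CS = "cs",
                 paths = c("A -> CS", "B -> CS"))
  expect_error(fit_pls(d, m), "[Cc]ollinear")

  m2 <- pls_model(CRF = "crf", CS = "cs", paths = "CRF -> CS")
  expect_error(fit_pls(d[0, ], m2))
  expect_error(fit_pls(dplyr::select(d, -crf), m2), "crf")

  # cyclic structural graphs are rejected at specification time
  expect_error(pls_model(A = "crf", B = "cs", paths = c("A -> B", "B -> A")),
               "acyclic")
})

test_that("interaction terms recover a known moderation coefficient", {
  set.seed(77)
  n <- 4000
  x <- rnorm(n); mo <- rnorm(n)
  y <- 0.4 * x + 0.3 * mo + 0.3 * scale(x * mo)[, 1] + rnorm(n, 0, 0.7)
  d <- tibble::tibble(x = x, m = mo, y = y)
  mod <- pls_model(X = "x", M = "m", Y = "y",
                   paths = c("X -> Y", "M -> Y"),
                   interactions = "X:M -> Y")
  f <- fit_pls(d, mod)
  est <- f$paths$estimate[f$paths$from == "X_x_M"]
  # the generative coefficient on the y (not standardised-y) scale is 0.3
  expect_equal(est, 0.3 / sd(y), tolerance = 0.12)

  # a constant moderator makes the product collinear with the main effect
  d0 <- tibble::tibble(x = x, m = 1 + 0 * x, y = y)
  expect_error(fit_pls(d0, mod))

  # zero-interaction simulation: bootstrap CI covers 0
  y2 <- 0.4 * x + 0.3 * mo + rnorm(n, 0, 0.8)
  d2 <- tibble::tibble(x = x, m = mo, y = y2)
  b <- bootstrap_pls(d2[1:400, ], mod, B = 199, seed = 42)
  td <- tidy(b)
  row <- td[td$from == "X_x_M", ]
  expect_true(row$conf.low <= 0 && row$conf.high >= 0)
})
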