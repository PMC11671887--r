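#' Simulate a raw tri-axial recording with known ground truth
#'
#' Builds a day's recording from a plan of segments, each a tri-axial
#' sinusoid whose post-filter 1-s epoch magnitude equals a prescribed level,
#' or exact zeros for non-wear.  Because the band-pass gain at the carrier
#' frequency is known analytically ([bandpass_gain()]), the sinusoid
#' amplitude is back-computed so that the filtered epoch mean lands exactly
#' on the requested milli-g level: for a sinusoid of amplitude `A` the epoch
#' mean of the rectified filtered magnitude is `A * gain` times the mean of
#' the rectified sampled sine (close to `2 / pi` at high sample rates).
#' Carriers with an integer number of half-cycles per second make the epoch
#' mean exact in every epoch; other carriers draw a warning.  A constant 1 g
#' gravity component is added to the z axis (removed by the filter).
#'
#' @param plan Tibble with columns `duration_min`, `level_mg` (0 for
#'   non-wear) and `freq_hz` (ignored for zero segments).  The plan
#'   describes one day and is repeated `n_days` times.
#' @param sample_rate Sampling frequency in Hz.
#' @param n_days Number of identical days to emit.
#' @param subject_id Subject label.
#' @param start_time Recording start (default a local midnight, so days are
#'   complete calendar days when the plan covers 1440 min).
#' @param low,high,order Band-pass design the ground truth is computed for.
#' @param nonwear_window Minutes of zeros that the downstream non-wear rule
#'   will flag; zero segments shorter than this are counted as wear in the
#'   lowest bin in the ground truth.
#' @param edges Spectrum bin edges for the ground-truth spectrum.
#' @return A list with `recording` (tibble `subject_id`, `time`, `x`, `y`,
#'   `z`) and `truth` (the analytically known per-person spectrum row, same
#'   schema as [summarize_days()] output).
#' @export
simulate_recording <- function(plan, sample_rate = 30, n_days = 1,
                               subject_id = "sim",
                               start_time = as.POSIXct("2020-01-06 00:00:00",
                                                       tz = "UTC"),
                               low = 0.29, high = 4, order = 4,
                               nonwear_window = 60, edges = spectrum_edges()) {
  plan <- as_tibble(plan)
  if (nrow(plan) == 0L) abort("Empty day plan.")
  stopifnot(all(c("duration_min", "level_mg") %in% names(plan)))
  if (any(plan$duration_min <= 0)) abort("Segment durations must be positive.")
  if (!"freq_hz" %in% names(plan)) plan$freq_hz <- NA_real_
  active <- plan$level_mg > 0
  if (any(active & !is.finite(plan$freq_hz))) {
    abort("Active segments need a carrier frequency.")
  }
  if (any(plan$freq_hz[active] >= sample_rate / 2)) {
    abort("Carrier frequency must be below the Nyquist frequency.")
  }
  gains <- rep(NA_real_, nrow(plan))
  gains[active] <- bandpass_gain(plan$freq_hz[active], sample_rate, low, high,
                                 order)
  if (any(gains[active] < 0.05)) {
    abort("Carrier in the filter stop band; epoch-level ground truth undefined.")
  }
  halfcycles <- 2 * plan$freq_hz[active]
  if (any(abs(halfcycles - round(halfcycles)) > 1e-9)) {
    warn("Carriers without an integer number of half-cycles per second give only approximate epoch means.")
  }
  axis_dir <- c(0.6, 0.48, 0.64)             # unit vector across the axes
  # epoch mean of the rectified sampled sinusoid (approaches 2/pi only as
  # the sampling grid refines; at low rates the discrete mean differs)
  rect_mean <- function(f) {
    mean(abs(sin(2 * pi * f * (seq_len(sample_rate) - 1) / sample_rate)))
  }
  seg <- function(dur, level, f, gain) {
    n <- as.integer(round(dur * 60 * sample_rate))
    if (level == 0) {
      matrix(0, n, 3)
    } else {
      rm_f <- rect_mean(f)
      if (rm_f < 0.1) {
        abort(sprintf("Carrier %g Hz aliases to near-zero epoch output.", f))
      }
      amp <- (level / 1000) / (gain * rm_f)
      s <- amp * sin(2 * pi * f * (seq_len(n) - 1) / sample_rate)
      cbind(s * axis_dir[1], s * axis_dir[2], s * axis_dir[3])
    }
  }
  day <- do.call(rbind, map(seq_len(nrow(plan)), function(i) {
    seg(plan$duration_min[i], plan$level_mg[i], plan$freq_hz[i], gains[i])
  }))
  xyz <- day[rep(seq_len(nrow(day)), n_days), , drop = FALSE]
  xyz[, 3] <- xyz[, 3] + 1                   # gravity on z, removed by the filter
  rec <- tibble(
    subject_id = subject_id,
    time = start_time + (seq_len(nrow(xyz)) - 1) / sample_rate,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  # analytic ground truth, per day
  labels <- spectrum_bin_names(edges)
  mins <- setNames(numeric(length(labels)), labels)
  nonwear <- 0
  breaks <- c(edges, Inf)
  for (i in seq_len(nrow(plan))) {
    if (plan$level_mg[i] == 0 && plan$duration_min[i] >= nonwear_window) {
      nonwear <- nonwear + plan$duration_min[i]
    } else {
      j <- findInterval(plan$level_mg[i], breaks)
      mins[j] <- mins[j] + plan$duration_min[i]
    }
  }
  wear_min <- sum(mins)
  truth <- bind_cols(
    tibble(subject_id = subject_id),
    as_tibble(as.list(mins)),
    tibble(nonwear = nonwear,
           n_valid_days = if (wear_min >= 600) n_days else 0L,
           valid = wear_min >= 600 && n_days >= 4)
  )
  list(recording = rec, truth = truth, plan = plan)
}

#' Simulate a cohort with known latent path structure
#'
#' Generates a per-person intensity-spectrum table and clinical panel whose
#' joint distribution follows the mediation structure the analysis targets:
#' a standard-normal latent activity score `PA` drives cardiorespiratory
#' fitness (`CRF = a * PA + sex/age effects + noise`), and the
#' cardiometabolic composite score follows
#' `CS = b * CRF + c_direct * PA + sex/age effects + noise`, all on
#' standardised latent scales.  Observable layers are then built on top:
#'
#' * The 22 intensity bins plus non-wear allocate 1440 min/day by a softmax
#'   of baseline log-weights (anchored to realistic cohort means: non-wear
#'   ~556, sedentary ~690, light ~106, moderate ~86, vigorous ~2 min/day)
#'   plus a loading profile that rises with intensity -- higher-intensity
#'   bins respond more strongly to the latent score -- plus smooth
#'   autocorrelated bin noise.  This induces the closed compositional,
#'   strongly collinear structure the PLS machinery exists to handle, with
#'   neighbouring bins more correlated than distant ones.
#' * The five risk factors are assigned Z-scores consistent with the target
#'   composite score plus idiosyncratic noise, then un-standardised with
#'   realistic means/SDs (waist 92.4 (11.9) cm, SBP 121 (16) mmHg, HbA1c
#'   35 (5) mmol/mol, TC:HDL ~3.4, TG 1.17 mmol/L), so that rebuilding the
#'   score with [composite_score()] recovers the generative structure and
#'   exercises the risk-score module.  The structural residual of CS is
#'   shrunk by exactly the variance of the averaged idiosyncratic noise, so
#'   the population path coefficients onto the rebuilt score equal the
#'   nominal ones.
#' * CRF is un-standardised to mean 33.9, SD 6.7 mL/min/kg; sex is
#'   Bernoulli(0.5) (0 = female, 1 = male), age uniform on 50--64 years.
#'
#' @param n Number of subjects (>= 50).
#' @param true_a Standardised path PA -> CRF.
#' @param true_b Standardised path CRF -> CS.
#' @param true_c_direct Standardised direct path PA -> CS.
#' @param sex_crf,age_crf,sex_cs,age_cs Standardised covariate paths.
#' @param loading Scale of the intensity loading profile (how strongly bin
#'   allocation responds to the latent activity score).
#' @param bin_noise_sd SD of the smooth per-bin log-weight noise.
#' @param bin_noise_rho Neighbour correlation of the bin noise (AR(1)).
#' @param idio_sd SD of the idiosyncratic risk-factor noise (z-units).
#' @param seed Integer seed; all randomness flows from it.
#' @param edges Spectrum bin edges.
#' @return A list with `spectrum` (schema of [summarize_days()] output),
#'   `panel`, and `truth` (the configuration, the latent scores per subject
#'   and the implied indirect/total/proportion-mediated values).
#' @export
simulate_cohort <- function(n = 4185, true_a = 0.387, true_b = 0.563,
                            true_c_direct = 0.047,
                            sex_crf = 0.43, age_crf = -0.20,
                            sex_cs = -0.30, age_cs = -0.12,
                            loading = 1, bin_noise_sd = 0.08,
                            bin_noise_rho = 0.7, idio_sd = 0.4,
                            seed = NULL, edges = spectrum_edges()) {
  if (n < 50) abort("Need n >= 50 subjects.")
  if (abs(true_c_direct + true_a * true_b) > 1) {
    abort("Implied total effect exceeds 1; infeasible path configuration.")
  }
  crf_resid <- 1 - (true_a^2 + sex_crf^2 + age_crf^2)
  if (crf_resid <= 0) abort("CRF paths leave no residual variance; infeasible.")
  # structural variance of CS, accounting for CRF's correlation with its parents
  var_cs_struct <- true_b^2 + true_c_direct^2 + sex_cs^2 + age_cs^2 +
    2 * true_b * (true_c_direct * true_a + sex_cs * sex_crf + age_cs * age_crf)
  # averaged idiosyncratic noise: waist, SBP, HbA1c at weight 1/4; the two
  # lipid variables at 1/8 each -> variance factor 3/16 + 2/64
  var_nu <- idio_sd^2 * (3 / 16 + 2 / 64)
  cs_resid <- 1 - var_cs_struct - var_nu
  if (cs_resid <= 0) abort("CS paths leave no residual variance; infeasible.")
  if (!is.null(seed)) set.seed(seed)

  sex <- rbinom(n, 1, 0.5)
  age <- runif(n, 50, 64)
  sex_z <- (sex - 0.5) / 0.5
  age_z <- (age - 57) / (14 / sqrt(12))
  pa <- rnorm(n)
  crf_z <- true_a * pa + sex_crf * sex_z + age_crf * age_z +
    rnorm(n, 0, sqrt(crf_resid))
  cs_z <- true_b * crf_z + true_c_direct * pa + sex_cs * sex_z +
    age_cs * age_z + rnorm(n, 0, sqrt(cs_resid))

  # ---- intensity spectrum: softmax allocation of 1440 min/day -------------
  base <- baseline_minutes(edges)
  beta <- c(loading * seq(-0.3, 1.2, length.out = length(edges)), -0.1)
  eps <- ar1_noise(n, length(base), bin_noise_rho, bin_noise_sd)
  logw <- matrix(log(base), n, length(base), byrow = TRUE) +
    outer(pa, beta) + eps
  w <- exp(logw)
  mins <- 1440 * w / rowSums(w)
  colnames(mins) <- names(base)
  ids <- sprintf("S%05d", seq_len(n))
  spectrum <- bind_cols(
    tibble(subject_id = ids), as_tibble(as.data.frame(mins)),
    tibble(n_valid_days = 7L, valid = TRUE)
  )

  # ---- clinical panel -----------------------------------------------------
  risk <- function() -cs_z + rnorm(n, 0, idio_sd)
  waist <- 92.4 + 11.9 * risk()
  sbp <- 121 + 16 * risk()
  hba1c <- 35 + 5 * risk()
  ratio <- pmax(1.2, 3.4 + 0.9 * risk())
  hdl <- pmax(0.5, 1.72 + 0.45 * rnorm(n))
  tg <- pmax(0.15, 1.17 + 0.45 * risk())
  panel <- tibble(
    subject_id = ids, waist = waist, sbp = sbp, tc = ratio * hdl, hdl = hdl,
    tg = tg, hba1c = hba1c, crf = 33.9 + 6.7 * crf_z, sex = sex, age = age
  )
  truth <- list(
    config = list(
      n = n, true_a = true_a, true_b = true_b, true_c_direct = true_c_direct,
      sex_crf = sex_crf, age_crf = age_crf, sex_cs = sex_cs, age_cs = age_cs,
      loading = loading, bin_noise_sd = bin_noise_sd,
      bin_noise_rho = bin_noise_rho, idio_sd = idio_sd, seed = seed
    ),
    indirect = true_a * true_b,
    total = true_c_direct + true_a * true_b,
    proportion_mediated = (true_a * true_b) / (true_c_direct + true_a * true_b),
    latents = tibble(subject_id = ids, pa = pa, crf_z = crf_z, cs_z = cs_z)
  )
  list(spectrum = spectrum, panel = panel, truth = truth)
}

# realistic baseline min/day allocation across the 22 bins + non-wear,
# anchored to cohort-scale coarse-class means and normalised to 1440
baseline_minutes <- function(edges = spectrum_edges()) {
  geom_split <- function(total, k, r) {
    w <- r^(seq_len(k) - 1)
    total * w / sum(w)
  }
  m <- c(
    480, 210,                       # sedentary: [0,25), [25,50)
    70, 36,                         # light: [50,100), [100,150)
    geom_split(86.4, 7, 0.68),      # moderate: [150,500) in 50-mg steps
    geom_split(1.95, 10, 0.55),     # vigorous: [500,1000)
    0.19                            # very vigorous: >= 1000
  )
  stopifnot(length(m) == length(edges))
  m <- c(m, 556)                    # non-wear (mostly sleep)
  m <- 1440 * m / sum(m)
  setNames(m, c(spectrum_bin_names(edges), "nonwear"))
}

# n x p matrix of AR(1)-correlated noise across columns (smooth over bins)
ar1_noise <- function(n, p, rho, sd) {
  e <- matrix(rnorm(n * p), n, p)
  if (p > 1) {
    for (j in 2:p) e[, j] <- rho * e[, j - 1] + sqrt(1 - rho^2) * e[, j]
  }
  sd * e
}
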