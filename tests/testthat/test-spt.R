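test_that("whisker rule removes exactly the hand-computed outlier", {
  bcf <- c(0.1, 0.2, 0.3, 0.4, 10, 0.15, 0.25, 0.35)
  s <- make_samples(cd_soil = 1, cd_rice = bcf, ph = 6)
  out <- remove_bcf_outliers(s, 1.5)
  # type-7 quartiles of the 8 values: Q1 = 0.1875, Q3 = 0.3625,
  # fences [-0.075, 0.625]: only the 10 falls outside
  expect_equal(out$removed$bcf, 10)
  expect_equal(nrow(out$kept), 7)
  expect_equal(out$kept$bcf, bcf[bcf != 10])  # order preserved
})

test_that("whisker rule degenerate cases keep everything", {
  s <- make_samples(cd_soil = 1, cd_rice = rep(0.3, 10), ph = 6)
  expect_equal(nrow(remove_bcf_outliers(s, 1.5)$removed), 0)
  s2 <- make_samples(cd_soil = 1,
                     cd_rice = c(0.1, 0.2, 0.3, 0.4, 10, 0.15, 0.25, 0.35),
                     ph = 6)
  expect_equal(nrow(remove_bcf_outliers(s2, Inf)$removed), 0)
  expect_error(remove_bcf_outliers(s2[1:5, ], 1.5), "at least 8")
})

test_that("noiseless data returns the generative coefficients exactly", {
  s <- generate_samples(noiseless_spec(n = 1000))
  fit <- fit_spt(s, pipeline_config(), remove_outliers = FALSE)
  expect_equal(unname(fit$coeffs["log_cdsoil"]), 0.857, tolerance = 1e-8)
  expect_equal(unname(fit$coeffs["ph"]), -0.074, tolerance = 1e-8)
  expect_equal(unname(fit$coeffs["(Intercept)"]), 0.083, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$n_removed_outliers, 0)
  # the normal-equations inverse is symmetric positive definite
  expect_equal(fit$xtx_inv, t(fit$xtx_inv), tolerance = 1e-12)
  expect_true(all(eigen(fit$xtx_inv, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  expect_gt(fit$df_resid, 0)
})

test_that("stepwise keeps null covariates out and true ones in", {
  # grain Cd depends only on soil Cd; pH, SOM, clay are noise
  set.seed(41)
  n <- 2000
  lcd <- rnorm(n, 0, 0.5)
  s <- as_paired_samples(data.frame(
    cd_soil = 10^lcd,
    cd_rice = 10^(0.8 * lcd + rnorm(n, 0, 0.3)),
    ph = runif(n, 4, 9),
    som = exp(rnorm(n, 1.2, 0.3)),
    clay = runif(n, 10, 50)
  ))
  fit <- fit_spt(s, pipeline_config(), remove_outliers = FALSE)
  expect_equal(fit$predictors, "log_cdsoil")

  # and with the transfer law active, pH is admitted
  s2 <- generate_samples(generator_spec(n_sites = 2000, rng_seed = 42L,
                                        residual_sd = 0.2,
                                        outlier_fraction = 0))
  fit2 <- fit_spt(s2, pipeline_config(), remove_outliers = FALSE)
  expect_true("ph" %in% fit2$predictors)
})

test_that("undersized inputs are refused", {
  s <- generate_samples(noiseless_spec(n = 5))
  expect_error(fit_spt(s, pipeline_config()), "at least 8")
  s9 <- generate_samples(noiseless_spec(n = 9))
  expect_error(fit_spt(s9, pipeline_config(), remove_outliers = FALSE),
               "at least 10")
})

test_that("prediction limits follow the t-interval formula", {
  # toy fit assembled by hand: one predictor, sigma 0.1, 50 residual df
  fit <- structure(list(
    coeffs = c("(Intercept)" = -0.5, log_cdsoil = 0.9),
    sigma = 0.1, df_resid = 50,
    xtx_inv = matrix(c(0.02, 0, 0, 0.05), 2, 2,
                     dimnames = list(c("(Intercept)", "log_cdsoil"),
                                     c("(Intercept)", "log_cdsoil"))),
    predictors = "log_cdsoil"
  ), class = "spt_fit")
  # at cd_soil = 1 the design row is (1, 0): leverage term 0.02
  point <- predict_interval(fit, 1, level = 0.5, side = "upper")
  expect_equal(point, -0.5)
  upper <- predict_interval(fit, 1, level = 0.95, side = "upper")
  expect_equal(upper, -0.5 + qt(0.95, 50) * 0.1 * sqrt(1.02),
               tolerance = 1e-12)
  lower <- predict_interval(fit, 1, level = 0.95, side = "lower")
  expect_equal(lower, -0.5 - qt(0.95, 50) * 0.1 * sqrt(1.02),
               tolerance = 1e-12)
  # one-sided 95% exceeds the plain z margin
  expect_gt(upper - point, qnorm(0.95) * 0.1)
})

test_that("a missing covariate is a contract error", {
  s <- generate_samples(noiseless_spec(n = 200))
  fit <- fit_spt(s, pipeline_config())
  expect_true("ph" %in% fit$predictors)
  expect_error(predict_interval(fit, 1, list(), 0.95, "upper"),
               "'ph' required")
})

test_that("threshold inversion matches the closed form at the median", {
  s <- generate_samples(noiseless_spec(n = 1000))
  fit <- fit_spt(s, pipeline_config())
  sc <- invert_threshold(fit, ph = 5.45, fqs = 0.2, protection = 0.5)
  expect_equal(sc, closed_form_sc50(5.45), tolerance = 1e-6)
  expect_equal(closed_form_sc50(5.45), 0.3615, tolerance = 1e-3)
})

test_that("inversion round-trips through the prediction limit", {
  s <- generate_samples(generator_spec(n_sites = 400, rng_seed = 44L,
                                       residual_sd = 0.25,
                                       outlier_fraction = 0))
  fit <- fit_spt(s, pipeline_config())
  for (case in list(c(5.0, 0.9), c(6.2, 0.5), c(7.8, 0.05))) {
    sc <- invert_threshold(fit, case[1], 0.2, case[2])
    lim <- predict_interval(fit, sc, list(ph = case[1]), case[2], "upper")
    expect_equal(lim, log10(0.2), tolerance = 1e-8)
  }
})

test_that("thresholds are monotone in protection and pH", {
  s <- generate_samples(generator_spec(n_sites = 400, rng_seed = 45L,
                                       residual_sd = 0.25,
                                       outlier_fraction = 0))
  fit <- fit_spt(s, pipeline_config())
  expect_lt(invert_threshold(fit, 6, 0.2, 0.95),
            invert_threshold(fit, 6, 0.2, 0.5))
  # negative pH coefficient: higher pH tolerates more soil Cd
  expect_lt(invert_threshold(fit, 5.5, 0.2, 0.5),
            invert_threshold(fit, 6.5, 0.2, 0.5))
})

test_that("a non-positive transfer slope refuses to invert", {
  fit <- structure(list(
    coeffs = c("(Intercept)" = 0.1, log_cdsoil = -0.3, ph = -0.05),
    sigma = 0.2, df_resid = 40,
    xtx_inv = diag(c(0.1, 0.05, 0.01)) |>
      (\(m) {dimnames(m) <- rep(list(c("(Intercept)", "log_cdsoil",
                                       "ph")), 2); m})(),
    predictors = c("log_cdsoil", "ph")
  ), class = "spt_fit")
  expect_error(invert_threshold(fit, 6, 0.2, 0.5), "positive")
})

test_that("band thresholds follow the closed-form median inversions", {
  s <- generate_samples(noiseless_spec(n = 1000))
  cfg <- pipeline_config(band_eval_ph = c(highly_acidic = 5.5,
                                          acidic = 6.5, neutral = 7.5,
                                          alkaline = 8.0))
  thr <- spt_band_thresholds(fit_spt(s, cfg), cfg)
  sc50 <- thr$sc[thr$protection == 0.5]
  expect_equal(sc50, closed_form_sc50(c(5.5, 6.5, 7.5, 8.0)),
               tolerance = 1e-6)
  # monotone in pH within each protection level; monotone in protection
  # (non-strict: a noiseless fit has zero interval width)
  for (p in unique(thr$protection)) {
    expect_true(all(diff(thr$sc[thr$protection == p]) > 0))
  }
  for (b in band_levels()) {
    sub <- thr[thr$band == b, ]
    expect_true(all(diff(sub$sc[order(-sub$protection)]) >= -1e-12))
  }
})

test_that("outlier removal recovers fit quality on contaminated data", {
  s <- generate_samples(generator_spec(n_sites = 1000, rng_seed = 46L))
  cfg <- pipeline_config()
  r2_all <- fit_spt(s, cfg, remove_outliers = FALSE)$r2
  fit <- fit_spt(s, cfg)
  expect_gt(fit$r2, r2_all)
  expect_gt(fit$n_removed_outliers, 0)
})
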