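test_that("log-normal MLE recovers its parameters and is a maximum", {
  set.seed(31)
  y <- rlnorm(1e4, 0, 1)
  fit <- fit_ssd_dist(y, "log_normal")
  expect_true(fit$converged)
  expect_equal(unname(fit$params["mu"]), 0, tolerance = 0.05)
  expect_equal(unname(fit$params["sigma"]), 1, tolerance = 0.05)
  # closed-form MLE: mean/SD (n denominator) of log y
  expect_equal(unname(fit$params["mu"]), mean(log(y)), tolerance = 1e-4)
  expect_equal(unname(fit$params["sigma"]),
               sqrt(mean((log(y) - mean(log(y)))^2)), tolerance = 1e-3)
  # likelihood dominates perturbed parameter pairs
  ll <- function(p) sum(dlnorm(y, p[1], p[2], log = TRUE))
  for (shift in list(c(0.05, 0), c(-0.05, 0), c(0, 0.05), c(0, -0.05))) {
    expect_gte(fit$loglik, ll(fit$params + shift))
  }
})

test_that("MLE agrees with an independent fitter for stats families", {
  skip_if_not_installed("fitdistrplus")
  set.seed(32)
  y <- rgamma(500, shape = 2.3, scale = 0.7)
  for (case in list(
    list(name = "gamma", ref = "gamma"),
    list(name = "weibull", ref = "weibull"),
    list(name = "log_normal", ref = "lnorm")
  )) {
    fit <- fit_ssd_dist(y, case$name)
    ref <- fitdistrplus::fitdist(y, case$ref)
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-4,
                 info = case$name)
  }
})

test_that("GOF battery matches the naive oracles and worked examples", {
  # the two-point uniform example: discrepancies enumerate to 0.25
  expect_equal(ks_statistic(c(0.25, 0.75)), 0.25)
  expect_equal(ks_brute(c(0.25, 0.75)), 0.25)

  set.seed(33)
  for (rep in 1:50) {
    u <- runif(20)
    expect_equal(ad_statistic(u), ad_brute(u), tolerance = 1e-10)
    expect_equal(ks_statistic(u), ks_brute(u), tolerance = 1e-10)
  }
})

test_that("information criteria follow the stated arithmetic", {
  set.seed(34)
  y <- rlnorm(30)
  fit <- manual_ssd_fit("log_normal", c(mu = 0, sigma = 1), -100, 30)
  fit <- gof_battery(fit, y)
  expect_equal(fit$aic, 204)
  expect_equal(fit$bic, 200 + 2 * log(30))
  expect_equal(fit$aicc, 204 + 12 / 27)

  # AICc undefined when n <= p + 1 (3-parameter family, 4 points)
  small <- manual_ssd_fit("burr3", c(theta = 1, c = 1, k = 1), -5, 4)
  small <- gof_battery(small, c(0.5, 1, 2, 3))
  expect_true(is.na(small$aicc))
  expect_gte(fit$aicc, fit$aic)
})

test_that("AICc delta selects the best model with stated tie-breaks", {
  fits <- list(
    manual_ssd_fit("burr3", c(theta = 1, c = 1, k = 1), -170, 100,
                   aicc = 346),
    manual_ssd_fit("log_logistic", c(alpha = 1, beta = 1), -173, 100,
                   aicc = 350),
    manual_ssd_fit("weibull", c(lambda = 1, kappa = 1), -175, 100,
                   aicc = 355)
  )
  best <- select_best(fits)
  expect_equal(best$distribution, "burr3")
  deltas <- vapply(attr(best, "fits"), function(f) f$delta, numeric(1))
  expect_equal(deltas, c(0, 4, 9))

  # exact tie between a 3- and a 2-parameter family: fewer parameters wins
  tie <- select_best(list(
    manual_ssd_fit("burr3", c(theta = 1, c = 1, k = 1), -10, 50,
                   aicc = 100),
    manual_ssd_fit("log_normal", c(mu = 0, sigma = 1), -10, 50, aicc = 100)
  ))
  expect_equal(tie$distribution, "log_normal")

  single <- select_best(list(
    manual_ssd_fit("gamma", c(shape = 1, scale = 1), -10, 50, aicc = 42)
  ))
  expect_equal(single$distribution, "gamma")
  expect_equal(single$delta, 0)
})

test_that("reciprocal BCFs group by band, ascending", {
  s <- make_samples(cd_soil = c(0.563, 1, 1), cd_rice = c(0.202, 2, 0.5),
                    ph = c(5.45, 5.5, 5.6))
  expect_warning(g <- inverse_bcf_groups(s), "empty pH band")
  expect_equal(g$highly_acidic, c(0.5, 0.563 / 0.202), tolerance = 1e-12)
  expect_equal(g$acidic, 2)
  expect_equal(g$highly_acidic[2], 2.787, tolerance = 1e-3)
  expect_false("neutral" %in% names(g))
})

test_that("SSD thresholds match closed-form quantiles", {
  ln <- manual_ssd_fit("log_normal", c(mu = 0, sigma = 1), -10, 50)
  expect_equal(ssd_threshold(ln, 0.95, 0.2),
               0.2 * exp(qnorm(0.05)), tolerance = 1e-10)
  expect_equal(0.2 * exp(qnorm(0.05)), 0.0386, tolerance = 1e-3)
  # protection 0.5 is the fitted median of 1/BCF times the FQS
  expect_equal(ssd_threshold(ln, 0.5, 0.2), 0.2 * exp(0))
  b3 <- manual_ssd_fit("burr3", c(theta = 1, c = 1, k = 1), -10, 50)
  expect_equal(ssd_threshold(b3, 0.5, 0.2), 0.2)
  expect_error(ssd_threshold(ln, 1.2, 0.2), "protection")
})

test_that("thresholds shrink as the protection level grows", {
  set.seed(35)
  y <- 1 / rlnorm(120, -0.5, 0.8)
  band <- fit_ssd_band(y)
  sc <- vapply(c(0.95, 0.5, 0.05),
               function(p) ssd_threshold(band$best, p, 0.2), numeric(1))
  expect_true(all(diff(sc) > 0))
})

test_that("matched families attain lower AD/KS than mismatched ones", {
  set.seed(36)
  ad_match <- ad_mis <- ks_match <- ks_mis <- numeric(20)
  for (i in 1:20) {
    y <- rlnorm(100, 0, 0.9)
    f_ln <- gof_battery(fit_ssd_dist(y, "log_normal"), y)
    f_wb <- gof_battery(fit_ssd_dist(y, "weibull"), y)
    ad_match[i] <- f_ln$ad; ad_mis[i] <- f_wb$ad
    ks_match[i] <- f_ln$ks; ks_mis[i] <- f_wb$ks
  }
  expect_lt(mean(ad_match), mean(ad_mis))
  expect_lt(mean(ks_match), mean(ks_mis))
})

test_that("degenerate or undersized data are refused", {
  expect_error(fit_ssd_dist(rep(1, 20), "gamma"), "degenerate")
  expect_error(fit_ssd_dist(c(1, 2, 3), "gamma"), "at least 8")
  expect_error(fit_ssd_dist(c(-1, seq_len(10)), "gamma"), "positive")
})

test_that("band fitting produces a goodness-of-fit table per family", {
  set.seed(37)
  y <- 1 / rlnorm(150, 0, 1)
  band <- fit_ssd_band(y)
  expect_s3_class(band, "ssd_band_fit")
  expect_equal(nrow(band$table), 6)
  expect_setequal(band$table$distribution, ssd_dist_names())
  ok <- band$table$converged
  expect_equal(sum(band$table$delta[ok] == 0), 1)
  expect_true(all(band$table$delta[ok] >= 0))
  curve <- ssd_curve_data(band, y)
  expect_equal(curve$empirical, seq_along(y) / (length(y) + 1))
  expect_true(all(abs(curve$fitted - curve$empirical) < 0.2))
})
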