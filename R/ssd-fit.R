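#' Fit one candidate distribution to positive sensitivity data
#'
#' Maximum-likelihood fit of one of the six candidate families to a vector
#' of reciprocal bioconcentration factors (or any positive data). Strictly
#' positive parameters are optimized on the log scale from moment-based
#' starting values; a small set of deterministic jittered starts guards
#' against local optima, and the best converged start is kept
#' (log-likelihood tolerance 1e-8). Non-convergence on every start marks
#' the fit failed rather than raising.
#'
#' @param y Positive numeric vector, `length(y) >= 8`.
#' @param distribution One of [ssd_dist_names()].
#' @param n_starts Number of optimizer starts (moment start plus
#'   deterministic offsets).
#' @return An object of class `ssd_fit`: list with `distribution`, named
#'   `params`, `loglik`, `n`, `converged`, plus GOF fields filled by
#'   [gof_battery()].
#' @export
fit_ssd_dist <- function(y, distribution, n_starts = 4) {
  distribution <- match.arg(distribution, ssd_dist_names())
  y <- as.numeric(y)
  if (length(y) < 8) {
    stop("need at least 8 observations to fit a distribution, got ",
         length(y), call. = FALSE)
  }
  if (any(!is.finite(y) | y <= 0)) {
    stop("all values must be positive and finite", call. = FALSE)
  }
  if (stats::sd(y) < .Machine$double.eps * max(y)) {
    stop("degenerate data: zero variance", call. = FALSE)
  }

  reg <- dist_registry(distribution)
  p_dim <- length(reg$par_names)
  on_log <- if (is.null(reg$log_scale)) rep(TRUE, p_dim) else reg$log_scale

  to_opt <- function(par) {
    par[on_log] <- log(par[on_log])
    par
  }
  from_opt <- function(th) {
    th[on_log] <- exp(th[on_log])
    th
  }
  nll <- function(th) {
    ld <- suppressWarnings(reg$logdens(y, from_opt(th)))
    if (any(!is.finite(ld))) return(1e10)
    -sum(ld)
  }

  start0 <- to_opt(reg$start(y))
  # deterministic offsets: reproducible multi-start without touching the RNG
  offsets <- outer(seq_len(max(n_starts - 1, 0)),
                   seq_len(p_dim),
                   function(i, j) 0.4 * sin(1.7 * i + 0.9 * j))
  starts <- c(list(start0),
              lapply(seq_len(nrow(offsets)),
                     function(i) start0 + offsets[i, ]))

  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B",
                   control = list(factr = 1e5, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e10) next
    if (is.null(best) || res$value < best$value - 1e-8) best <- res
  }

  fit <- list(distribution = distribution, n = length(y))
  if (is.null(best)) {
    fit$converged <- FALSE
    fit$params <- stats::setNames(rep(NA_real_, p_dim), reg$par_names)
    fit$loglik <- NA_real_
  } else {
    fit$converged <- TRUE
    fit$params <- stats::setNames(from_opt(best$par), reg$par_names)
    fit$loglik <- -best$value
  }
  class(fit) <- "ssd_fit"
  fit
}

#' Anderson-Darling statistic from CDF-transformed values
#'
#' `A2 = -n - (1/n) sum_i (2i-1) [ln u_(i) + ln(1 - u_(n+1-i))]` with
#' `u_(i)` the ascending ordered CDF values.
#'
#' @param u Values of the fitted CDF at the data, in (0, 1) (any order).
#' @return The A2 statistic; `NA` if it is not finite.
#' @export
ad_statistic <- function(u) {
  u <- sort(u)
  n <- length(u)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(u) + log(1 - u[n + 1 - i])))
  if (is.finite(a2)) a2 else NA_real_
}

#' Kolmogorov-Smirnov statistic from CDF-transformed values
#'
#' `D = max_i max(i/n - u_(i), u_(i) - (i-1)/n)`.
#'
#' @inheritParams ad_statistic
#' @return The KS statistic, in `[0, 1]`.
#' @export
ks_statistic <- function(u) {
  u <- sort(u)
  n <- length(u)
  i <- seq_len(n)
  max(pmax(i / n - u, u - (i - 1) / n))
}

#' Goodness-of-fit battery for a fitted distribution
#'
#' Computes the Anderson-Darling and Kolmogorov-Smirnov statistics (CDF
#' values clamped to `[1e-12, 1 - 1e-12]` first) plus AIC, BIC and the
#' small-sample AICc, with the parameter count `p` equal to the number of
#' distribution parameters (3 for Burr III, 2 otherwise). AICc is reported
#' missing when `n <= p + 1`.
#'
#' @param fit An `ssd_fit`.
#' @param y The data the fit was computed on.
#' @return The `ssd_fit` with fields `ad`, `ks`, `aic`, `bic`, `aicc`
#'   filled in.
#' @export
gof_battery <- function(fit, y) {
  stopifnot(inherits(fit, "ssd_fit"))
  if (!isTRUE(fit$converged)) {
    fit[c("ad", "ks", "aic", "bic", "aicc")] <- NA_real_
    return(fit)
  }
  reg <- dist_registry(fit$distribution)
  u <- reg$cdf(sort(y), fit$params)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  n <- length(y)
  p <- length(fit$params)
  fit$ad <- ad_statistic(u)
  fit$ks <- ks_statistic(u)
  fit$aic <- -2 * fit$loglik + 2 * p
  fit$bic <- -2 * fit$loglik + p * log(n)
  fit$aicc <- if (n > p + 1) fit$aic + 2 * p * (p + 1) / (n - p - 1)
              else NA_real_
  fit
}

#' Select the best-fitting distribution in one pH band
#'
#' Assigns each converged candidate its AICc delta (AICc minus the band
#' minimum) and returns the delta-zero fit. Ties are broken in favour of
#' fewer parameters, then lexicographic family name. Failed fits are
#' excluded from the delta computation.
#'
#' @param fits List of `ssd_fit` objects for one band (GOF fields filled).
#' @return The selected `ssd_fit`; every element of `fits` gains a `delta`
#'   field via the attribute `"fits"` of the return value.
#' @export
select_best <- function(fits) {
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$aicc),
               logical(1))
  if (!any(ok)) stop("no converged candidate distribution", call. = FALSE)
  aicc <- vapply(fits, function(f) if (is.finite(f$aicc %||% NA)) f$aicc
                 else Inf, numeric(1))
  m <- min(aicc[ok])
  for (i in seq_along(fits)) {
    fits[[i]]$delta <- if (ok[i]) fits[[i]]$aicc - m else NA_real_
  }
  cand <- which(ok & aicc - m <= 0)
  if (length(cand) > 1) {
    np <- vapply(fits[cand], function(f) length(f$params), numeric(1))
    cand <- cand[np == min(np)]
    if (length(cand) > 1) {
      nm <- vapply(fits[cand], function(f) f$distribution, character(1))
      cand <- cand[order(nm)][1]
    }
  }
  best <- fits[[cand[1]]]
  attr(best, "fits") <- fits
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group reciprocal BCF values by pH band
#'
#' @param samples A `paired_samples` tibble.
#' @return Named list (one element per non-empty band, in band order) of
#'   ascending `1/BCF = cd_soil / cd_rice` values. Empty bands are dropped
#'   with a warning.
#' @export
inverse_bcf_groups <- function(samples) {
  stopifnot(all(samples$bcf > 0))
  groups <- split(1 / samples$bcf, samples$band)
  empty <- names(groups)[vapply(groups, length, integer(1)) == 0]
  if (length(empty)) {
    warning("empty pH band(s) excluded from SSD fitting: ",
            toString(empty), call. = FALSE)
  }
  lapply(groups[setdiff(names(groups), empty)], sort)
}

#' Fit all candidate distributions to one band's 1/BCF values
#'
#' @param y Ascending positive values (reciprocal BCFs of one band).
#' @param distributions Candidate family names; defaults to all six.
#' @return An object of class `ssd_band_fit`: list with `fits` (all
#'   candidates, GOF and delta filled), `best` (selected `ssd_fit`),
#'   and `table`, a tibble shaped like a goodness-of-fit report
#'   (distribution, AD, KS, AIC, BIC, AICc, delta, converged).
#' @export
fit_ssd_band <- function(y, distributions = ssd_dist_names()) {
  fits <- lapply(distributions, function(d) {
    f <- tryCatch(fit_ssd_dist(y, d), error = function(e) {
      structure(list(distribution = d, n = length(y), converged = FALSE,
                     params = NA_real_, loglik = NA_real_),
                class = "ssd_fit")
    })
    gof_battery(f, y)
  })
  names(fits) <- distributions
  best <- select_best(fits)
  fits <- attr(best, "fits")
  attr(best, "fits") <- NULL
  tab <- tibble::tibble(
    distribution = distributions,
    ad = vapply(fits, function(f) f$ad %||% NA_real_, numeric(1)),
    ks = vapply(fits, function(f) f$ks %||% NA_real_, numeric(1)),
    aic = vapply(fits, function(f) f$aic %||% NA_real_, numeric(1)),
    bic = vapply(fits, function(f) f$bic %||% NA_real_, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc %||% NA_real_, numeric(1)),
    delta = vapply(fits, function(f) f$delta %||% NA_real_, numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1))
  )
  structure(list(fits = fits, best = best, table = tab, n = length(y)),
            class = "ssd_band_fit")
}

#' Fit species sensitivity distributions per pH band
#'
#' Groups `1/BCF` by GB 15618-2018 pH band and fits the six candidate
#' families to each band with at least 8 sites; smaller bands are skipped
#' with a warning.
#'
#' @param samples A `paired_samples` tibble.
#' @param distributions Candidate family names.
#' @return Named list of `ssd_band_fit`, one per fitted band.
#' @export
fit_ssd <- function(samples, distributions = ssd_dist_names()) {
  groups <- inverse_bcf_groups(samples)
  small <- names(groups)[vapply(groups, length, integer(1)) < 8]
  if (length(small)) {
    warning("band(s) with fewer than 8 sites skipped: ", toString(small),
            call. = FALSE)
    groups <- groups[setdiff(names(groups), small)]
  }
  lapply(groups, fit_ssd_band, distributions = distributions)
}

#' Back-calculate a soil threshold from a fitted sensitivity distribution
#'
#' Returns `fqs * Q(1 - protection)` where `Q` is the fitted quantile
#' function of `1/BCF`: the soil Cd concentration at which the fitted
#' fraction of sites whose grain stays at or below the food quality
#' standard equals the protection level.
#'
#' @param fit A converged `ssd_fit`.
#' @param protection Fraction of rice production to protect, in (0, 1).
#' @param fqs Food quality standard, mg kg-1 DW.
#' @return Soil Cd threshold, mg kg-1 DW.
#' @export
ssd_threshold <- function(fit, protection, fqs) {
  stopifnot(inherits(fit, "ssd_fit"), isTRUE(fit$converged))
  if (any(protection <= 0 | protection >= 1)) {
    stop("protection must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(fqs > 0)
  reg <- dist_registry(fit$distribution)
  unname(fqs * reg$quantile(1 - protection, fit$params))
}

#' SSD-derived soil thresholds per pH band and protection level
#'
#' @param ssd_fits Named list of `ssd_band_fit` from [fit_ssd()].
#' @param config A `pipeline_config`.
#' @return Tibble with columns `band`, `protection`, `label`,
#'   `distribution`, `sc` (mg kg-1).
#' @export
ssd_band_thresholds <- function(ssd_fits, config = pipeline_config()) {
  rows <- list()
  for (band in names(ssd_fits)) {
    best <- ssd_fits[[band]]$best
    for (p in config$protection_levels) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        band = band, protection = p, label = sc_label(p),
        distribution = best$distribution,
        sc = ssd_threshold(best, p, config$fqs)
      )
    }
  }
  do.call(rbind, rows)
}

#' @export
print.ssd_fit <- function(x, ...) {
  cat("SSD fit:", x$distribution, "(n =", x$n, ")\n")
  if (isTRUE(x$converged)) {
    cat("  params:", paste(names(x$params), signif(x$params, 4), sep = "=",
                           collapse = ", "), "\n")
    cat("  loglik:", signif(x$loglik, 6), "\n")
    if (!is.null(x$aicc)) {
      cat(sprintf("  AD %.3g  KS %.3g  AIC %.4g  BIC %.4g  AICc %.4g\n",
                  x$ad, x$ks, x$aic, x$bic, x$aicc))
    }
  } else {
    cat("  (fit failed to converge)\n")
  }
  invisible(x)
}

#' @export
print.ssd_band_fit <- function(x, ...) {
  cat("SSD candidate fits (n =", x$n, "), best:", x$best$distribution, "\n")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Empirical plotting positions against the fitted CDF
#'
#' Plotting positions `i / (n + 1)` against the selected fit's CDF,
#' ready for an SSD curve plot.
#'
#' @param band_fit An `ssd_band_fit`.
#' @param y The band's ascending `1/BCF` values.
#' @return Tibble with `value`, `empirical`, `fitted`.
#' @export
ssd_curve_data <- function(band_fit, y) {
  y <- sort(y)
  reg <- dist_registry(band_fit$best$distribution)
  tibble::tibble(
    value = y,
    empirical = seq_along(y) / (length(y) + 1),
    fitted = reg$cdf(y, band_fit$best$params)
  )
}
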