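#' Remove BCF outliers by the boxplot whisker rule
#'
#' Tukey fences on the pooled untransformed BCF values: a site is removed
#' when its BCF lies below `Q1 - k IQR` or above `Q3 + k IQR`, with
#' quartiles by linear interpolation (type 7). Mirrors the survey practice
#' of discarding sites outside the whiskers of the BCF boxplot before
#' fitting the transfer model.
#'
#' @param samples A `paired_samples` tibble of at least 8 rows.
#' @param whisker_k Whisker multiplier `k` (1.5 is the boxplot default;
#'   `Inf` removes nothing).
#' @return List with `kept` and `removed` (`paired_samples`, input order
#'   preserved).
#' @export
remove_bcf_outliers <- function(samples, whisker_k = 1.5) {
  if (nrow(samples) < 8) {
    stop("need at least 8 samples for whisker-based outlier removal, got ",
         nrow(samples), call. = FALSE)
  }
  stopifnot(whisker_k > 0)
  q <- stats::quantile(samples$bcf, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fence <- if (iqr == 0) q else c(q[1] - whisker_k * iqr,
                                  q[2] + whisker_k * iqr)
  out <- samples$bcf < fence[1] | samples$bcf > fence[2]
  list(kept = samples[!out, , drop = FALSE],
       removed = samples[out, , drop = FALSE])
}

spt_predictor_cols <- function(samples) {
  d <- data.frame(
    log_cdrice = log10(samples$cd_rice),
    log_cdsoil = log10(samples$cd_soil),
    ph = samples$ph
  )
  if (any(is.finite(samples$som)) && all(samples$som > 0, na.rm = TRUE)) {
    d$log_som <- log10(samples$som)
  }
  if (any(is.finite(samples$clay)) && all(samples$clay > 0, na.rm = TRUE)) {
    d$log_clay <- log10(samples$clay)
  }
  d
}

# p-values of each non-forced term in an lm fit; non-finite (degenerate
# residual variance, aliased terms) counts as "no evidence", p = 1
term_p_values <- function(fit, terms) {
  s <- suppressWarnings(summary(fit))$coefficients
  p <- stats::setNames(rep(1, length(terms)), terms)
  present <- intersect(terms, rownames(s))
  p[present] <- s[present, 4]
  p[!is.finite(p)] <- 1
  p
}

#' Fit the Freundlich-type soil-plant transfer regression
#'
#' Ordinary least squares of `log10 Cd_rice` on `log10 Cd_soil` plus
#' stepwise-selected soil covariates (pH, log10 SOM, log10 clay), after
#' whisker-rule removal of BCF outliers. `log10 Cd_soil` is the core
#' transfer term and is never eligible for removal. Selection is
#' bidirectional on partial-F p-values: the candidate with the smallest
#' p-value is added while below `stepwise_enter_p`, any included term
#' whose p-value exceeds `stepwise_remove_p` is dropped, iterated to a
#' fixed point.
#'
#' @param samples A `paired_samples` tibble.
#' @param config A `pipeline_config` (whisker and stepwise settings).
#' @param remove_outliers Apply the BCF whisker rule first (default TRUE).
#' @return An object of class `spt_fit`: coefficients (`(Intercept)` plus
#'   predictors), `sigma` (residual SE, log10 units), `df_resid`,
#'   `xtx_inv` (inverse normal-equations matrix, for prediction
#'   intervals), `r2`, `n_used`, `n_removed_outliers`, `predictors`,
#'   `removed_sites`.
#' @export
fit_spt <- function(samples, config = pipeline_config(),
                    remove_outliers = TRUE) {
  removed_sites <- character(0)
  if (remove_outliers) {
    if (nrow(samples) < 8) {
      stop("need at least 8 samples, got ", nrow(samples), call. = FALSE)
    }
    split_ <- remove_bcf_outliers(samples, config$whisker_k)
    removed_sites <- split_$removed$site_id
    samples <- split_$kept
  }
  if (nrow(samples) < 10) {
    stop("need at least 10 samples after outlier removal, got ",
         nrow(samples), call. = FALSE)
  }

  d <- spt_predictor_cols(samples)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  candidates <- setdiff(names(d), c("log_cdrice", "log_cdsoil"))
  forced <- "log_cdsoil"

  current <- character(0)
  for (iter in seq_len(50)) {
    changed <- FALSE
    # forward: best candidate by p-value of its coefficient when added
    pool <- setdiff(candidates, current)
    if (length(pool)) {
      p_add <- vapply(pool, function(term) {
        f <- stats::lm(stats::reformulate(c(forced, current, term),
                                          "log_cdrice"), data = d)
        if (anyNA(stats::coef(f))) return(1)
        term_p_values(f, term)
      }, numeric(1))
      if (min(p_add) < config$stepwise_enter_p) {
        current <- c(current, pool[which.min(p_add)])
        changed <- TRUE
      }
    }
    # backward: drop the worst included term above the removal threshold
    if (length(current)) {
      f <- stats::lm(stats::reformulate(c(forced, current), "log_cdrice"),
                     data = d)
      p_cur <- term_p_values(f, current)
      if (max(p_cur) > config$stepwise_remove_p) {
        current <- setdiff(current, names(which.max(p_cur)))
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  predictors <- c(forced, current)
  fit <- stats::lm(stats::reformulate(predictors, "log_cdrice"), data = d)
  if (anyNA(stats::coef(fit))) {
    stop("perfect collinearity among predictors: ",
         toString(names(stats::coef(fit))[is.na(stats::coef(fit))]),
         call. = FALSE)
  }
  s <- suppressWarnings(summary(fit))
  structure(
    list(coeffs = stats::coef(fit),
         sigma = s$sigma,
         df_resid = fit$df.residual,
         xtx_inv = s$cov.unscaled,
         r2 = s$r.squared,
         n_used = nrow(d),
         n_removed_outliers = length(removed_sites),
         predictors = predictors,
         removed_sites = removed_sites,
         covariate_medians = list(
           som = if ("log_som" %in% names(d)) 10^stats::median(d$log_som)
                 else NA_real_,
           clay = if ("log_clay" %in% names(d)) 10^stats::median(d$log_clay)
                  else NA_real_
         )),
    class = "spt_fit"
  )
}

# design matrix for new sites: intercept + predictors, coefficient order;
# cd_soil and covariate entries recycle against each other
spt_design_matrix <- function(fit, cd_soil, covariates) {
  cols <- list(log_cdsoil = log10(cd_soil))
  if ("ph" %in% fit$predictors) {
    if (is.null(covariates$ph)) stop("covariate 'ph' required", call. = FALSE)
    cols$ph <- covariates$ph
  }
  if ("log_som" %in% fit$predictors) {
    if (is.null(covariates$som)) stop("covariate 'som' required",
                                      call. = FALSE)
    cols$log_som <- log10(covariates$som)
  }
  if ("log_clay" %in% fit$predictors) {
    if (is.null(covariates$clay)) stop("covariate 'clay' required",
                                       call. = FALSE)
    cols$log_clay <- log10(covariates$clay)
  }
  n <- max(vapply(cols, length, integer(1)))
  x <- cbind("(Intercept)" = 1,
             do.call(cbind, lapply(cols[fit$predictors],
                                   function(v) rep_len(v, n))))
  x
}

#' One-sided prediction limit of the transfer model
#'
#' Returns `yhat + t(level, df) sigma sqrt(1 + x0' (X'X)^-1 x0)` for the
#' upper side (the Student quantile is negated for the lower side): the
#' one-sided prediction limit for a new site's `log10 Cd_rice` at the
#' given soil Cd and covariates. At `level = 0.5` the upper limit equals
#' the point prediction exactly.
#'
#' @param fit An `spt_fit`.
#' @param cd_soil Soil Cd, mg kg-1 DW (vectorized).
#' @param covariates Named list supplying every selected covariate
#'   (`ph`, and `som`/`clay` if selected; natural units; recycled
#'   against `cd_soil`).
#' @param level One-sided coverage level, in (0, 1).
#' @param side `"upper"` or `"lower"`.
#' @return Prediction limit(s) in log10 mg kg-1.
#' @export
predict_interval <- function(fit, cd_soil, covariates = list(),
                             level = 0.95, side = c("upper", "lower")) {
  stopifnot(inherits(fit, "spt_fit"), all(cd_soil > 0),
            level > 0, level < 1)
  side <- match.arg(side)
  x0 <- spt_design_matrix(fit, cd_soil, covariates)
  yhat <- drop(x0 %*% fit$coeffs)
  leverage <- rowSums((x0 %*% fit$xtx_inv) * x0)
  tq <- stats::qt(level, df = fit$df_resid)
  half <- tq * fit$sigma * sqrt(1 + leverage)
  if (side == "upper") yhat + half else yhat - half
}

#' Invert the transfer model into a soil threshold
#'
#' Finds the soil Cd concentration at which the one-sided upper prediction
#' limit for grain Cd equals the food quality standard: under the
#' predictive t distribution, grain at a site with this soil concentration
#' stays at or below the FQS with probability `protection`. Solved by
#' bisection on log10 soil Cd over `[-6, 3]` to 1e-10 log10 units;
#' requires a positive coefficient on `log10 Cd_soil` (monotone transfer).
#'
#' @param fit An `spt_fit`.
#' @param ph Soil pH at which to evaluate.
#' @param fqs Food quality standard, mg kg-1 DW.
#' @param protection Protection level in (0, 1).
#' @param covariates Extra covariates (`som`, `clay`) if selected.
#' @return Soil Cd threshold, mg kg-1 DW.
#' @export
invert_threshold <- function(fit, ph, fqs, protection,
                             covariates = list()) {
  stopifnot(inherits(fit, "spt_fit"), fqs > 0,
            protection > 0, protection < 1)
  b <- unname(fit$coeffs["log_cdsoil"])
  if (!is.finite(b) || b <= 0) {
    stop("coefficient on log10 Cd_soil must be positive to invert the ",
         "transfer model (got ", signif(b, 4), ")", call. = FALSE)
  }
  cov <- covariates
  cov$ph <- ph
  target <- log10(fqs)
  g <- function(l) {
    predict_interval(fit, 10^l, cov, level = protection, side = "upper") -
      target
  }
  lo <- -6; hi <- 3
  g_lo <- g(lo); g_hi <- g(hi)
  if (is.na(g_lo) || is.na(g_hi) || g_lo * g_hi > 0) {
    stop("no root in log10 soil-Cd bracket [-6, 3]", call. = FALSE)
  }
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (g_lo * g(mid) <= 0) hi <- mid else lo <- mid
  }
  10^((lo + hi) / 2)
}

#' SPT-derived soil thresholds per pH band and protection level
#'
#' Evaluates [invert_threshold()] at each band's representative pH
#' (`config$band_eval_ph`, defaulting to the band's conservative low
#' edge) for every configured protection level. Requires pH among the
#' selected predictors. Covariates other than pH (SOM, clay, when the
#' stepwise search admitted them) are held at the medians of the fitting
#' data unless supplied explicitly.
#'
#' @param fit An `spt_fit` whose predictors include `ph`.
#' @param config A `pipeline_config`.
#' @param covariates Values for extra selected covariates (`som`,
#'   `clay`); defaults to the fit's stored medians.
#' @return Tibble with columns `band`, `protection`, `label`, `eval_ph`,
#'   `sc` (mg kg-1).
#' @export
spt_band_thresholds <- function(fit, config = pipeline_config(),
                                covariates = list()) {
  if (!"ph" %in% fit$predictors) {
    stop("fitted model does not include pH; band-wise thresholds are ",
         "undefined", call. = FALSE)
  }
  if ("log_som" %in% fit$predictors && is.null(covariates$som)) {
    covariates$som <- fit$covariate_medians$som
  }
  if ("log_clay" %in% fit$predictors && is.null(covariates$clay)) {
    covariates$clay <- fit$covariate_medians$clay
  }
  rows <- list()
  for (band in band_levels()) {
    eval_ph <- config$band_eval_ph[[band]]
    for (p in config$protection_levels) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        band = band, protection = p, label = sc_label(p), eval_ph = eval_ph,
        sc = invert_threshold(fit, eval_ph, config$fqs, p, covariates)
      )
    }
  }
  do.call(rbind, rows)
}

#' @export
print.spt_fit <- function(x, ...) {
  cat("Soil-plant transfer fit (log10 scale)\n")
  eq <- paste(sprintf("%+.4g*%s", x$coeffs[-1], names(x$coeffs)[-1]),
              collapse = " ")
  cat("  log10[Cd_rice] =", eq, sprintf("%+.4g", x$coeffs[1]), "\n")
  cat(sprintf("  R2 = %.3f, sigma = %.4g, n = %d (removed %d outliers)\n",
              x$r2, x$sigma, x$n_used, x$n_removed_outliers))
  invisible(x)
}
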