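# Build a paired_samples table from bare vectors (recycled to max length)
make_samples <- function(cd_soil, cd_rice, ph, som = NA_real_,
                         clay = NA_real_) {
  n <- max(length(cd_soil), length(cd_rice), length(ph))
  suppressWarnings(as_paired_samples(data.frame(
    cd_soil = rep_len(cd_soil, n),
    cd_rice = rep_len(cd_rice, n),
    ph = rep_len(ph, n),
    som = rep_len(som, n),
    clay = rep_len(clay, n)
  )))
}

# Exact-transfer-law samples: no residual noise, no outliers
noiseless_spec <- function(n = 1000, seed = 7L, ...) {
  generator_spec(n_sites = n, residual_sd = 0, outlier_fraction = 0,
                 rng_seed = seed, ...)
}

# closed-form median-inversion soil threshold for coefficients (b, a, k)
closed_form_sc50 <- function(ph, fqs = 0.2, b = 0.857, a = -0.074,
                             k = 0.083) {
  10^((log10(fqs) - k - a * ph) / b)
}

# build a minimal ssd_fit by hand (for GOF/selection arithmetic tests)
manual_ssd_fit <- function(distribution, params, loglik, n,
                           aicc = NULL) {
  f <- structure(
    list(distribution = distribution, params = params, loglik = loglik,
         n = n, converged = TRUE),
    class = "ssd_fit"
  )
  if (!is.null(aicc)) f$aicc <- aicc
  f
}
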