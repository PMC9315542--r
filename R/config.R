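#' Pipeline configuration
#'
#' Bundles the tunable constants of the criteria derivation. Defaults encode
#' the study conditions: the Chinese food quality standard for rice grain
#' (FQS, 0.2 mg kg-1 DW), protection levels 0.95/0.50/0.05 (named SC_5,
#' SC_50 and SC_95 respectively -- SC_x leaves x% of rice production
#' unprotected), Tukey's k = 1.5 whisker rule for BCF outliers, classic
#' p-value stepwise thresholds (enter 0.05 / remove 0.10), and the
#' representative pH at which soil-plant-transfer thresholds are evaluated
#' within each band (the band's conservative low edge; 4.0 for the open
#' acid end, 8.0 for the open alkaline end).
#'
#' @param fqs Food quality standard for rice grain, mg kg-1 DW.
#' @param protection_levels Fractions in (0, 1); the fraction of rice
#'   production protected at each criterion.
#' @param whisker_k Boxplot whisker multiplier for BCF outlier removal.
#' @param stepwise_enter_p,stepwise_remove_p Partial-F p-value thresholds
#'   for bidirectional stepwise selection.
#' @param band_eval_ph Named numeric vector (one value per pH band) giving
#'   the pH at which SPT thresholds are evaluated.
#' @param rng_seed Integer seed for any stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fqs = 0.2,
                            protection_levels = c(0.95, 0.50, 0.05),
                            whisker_k = 1.5,
                            stepwise_enter_p = 0.05,
                            stepwise_remove_p = 0.10,
                            band_eval_ph = c(highly_acidic = 4.0,
                                             acidic = 5.5,
                                             neutral = 6.5,
                                             alkaline = 8.0),
                            rng_seed = 1L) {
  band_eval_ph <- unlist(band_eval_ph)
  stopifnot(is.numeric(fqs), length(fqs) == 1, fqs > 0)
  stopifnot(all(protection_levels > 0), all(protection_levels < 1))
  stopifnot(whisker_k > 0)
  stopifnot(stepwise_enter_p > 0, stepwise_enter_p < 1,
            stepwise_remove_p > 0, stepwise_remove_p < 1)
  if (!all(band_levels() %in% names(band_eval_ph))) {
    stop("band_eval_ph must name every pH band: ",
         toString(band_levels()), call. = FALSE)
  }
  structure(
    list(fqs = fqs,
         protection_levels = sort(protection_levels, decreasing = TRUE),
         whisker_k = whisker_k,
         stepwise_enter_p = stepwise_enter_p,
         stepwise_remove_p = stepwise_remove_p,
         band_eval_ph = band_eval_ph[band_levels()],
         rng_seed = as.integer(rng_seed)),
    class = "pipeline_config"
  )
}

# SC_x label for a protection level: SC_5 protects 95%, SC_95 protects 5%
sc_label <- function(protection) {
  sprintf("SC_%g", round(100 * (1 - protection)))
}

#' Read a pipeline configuration from JSON
#'
#' @param path Path to a JSON document whose fields mirror the arguments of
#'   [pipeline_config()]; absent fields keep their defaults.
#' @return A `pipeline_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown config field(s): ", toString(unknown),
            call. = FALSE)
  }
  do.call(pipeline_config, raw[intersect(names(raw), known)])
}

#' Write a pipeline configuration to JSON
#'
#' @param config A `pipeline_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$band_eval_ph <- as.list(cfg$band_eval_ph)  # keep band names in JSON
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Criteria pipeline configuration\n")
  cat("  FQS:", x$fqs, "mg/kg; protection levels:",
      toString(x$protection_levels), "\n")
  cat("  whisker k:", x$whisker_k,
      "; stepwise enter/remove p:", x$stepwise_enter_p, "/",
      x$stepwise_remove_p, "\n")
  cat("  band eval pH:",
      paste(names(x$band_eval_ph), x$band_eval_ph, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
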