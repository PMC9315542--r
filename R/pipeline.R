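#' Run the full criteria-derivation pipeline
#'
#' Chains the stages on one table of paired samples: BCF-outlier removal
#' and the stepwise Freundlich-type transfer fit, per-band inversion
#' through one-sided prediction intervals; per-band SSD fitting of
#' reciprocal BCFs with AICc selection and back-calculation from the FQS;
#' the minimum-rule combination into soil criteria; and the suitability
#' and exceeding-factor validation against the same samples.
#'
#' @param samples A `paired_samples` tibble.
#' @param config A `pipeline_config`.
#' @return Object of class `criteria_pipeline`: list with `spt_fit`,
#'   `spt_thresholds`, `ssd_fits`, `ssd_thresholds`, `criteria`,
#'   `suitability` (at protection 0.5), `exceedance` (conditional on
#'   SC_95), `spearman`, and `config`.
#' @export
run_pipeline <- function(samples, config = pipeline_config()) {
  spt <- fit_spt(samples, config)
  if ("ph" %in% spt$predictors) {
    spt_thr <- spt_band_thresholds(spt, config)
  } else {
    # pH missed the stepwise gate: band-wise transfer thresholds are
    # undefined, criteria fall back to the SSD route alone
    warning("pH not selected by the stepwise search; criteria derive ",
            "from the SSD route only", call. = FALSE)
    spt_thr <- NULL
  }
  ssd <- fit_ssd(samples)
  ssd_thr <- ssd_band_thresholds(ssd, config)
  criteria <- if (is.null(spt_thr)) {
    suppressWarnings(derive_criteria(NULL, ssd_thr, config))
  } else {
    derive_criteria(spt_thr, ssd_thr, config)
  }
  suitability <- classify_suitability(samples, criteria, protection = 0.5,
                                      fqs = config$fqs)
  exceedance <- exceeding_factors(samples, config$fqs, criteria,
                                  protection = 0.05)
  structure(
    list(spt_fit = spt, spt_thresholds = spt_thr,
         ssd_fits = ssd, ssd_thresholds = ssd_thr,
         criteria = criteria, suitability = suitability,
         exceedance = exceedance,
         spearman = spearman_report(samples),
         config = config),
    class = "criteria_pipeline"
  )
}

#' @export
print.criteria_pipeline <- function(x, ...) {
  print(x$spt_fit)
  cat("\n")
  print(x$criteria)
  invisible(x)
}

# strip classes/attributes so any pipeline product serializes cleanly
as_plain <- function(x) {
  if (is.data.frame(x)) {
    df <- as.data.frame(x)
    attr(df, "fqs") <- NULL
    attr(df, "config") <- NULL
    return(df)
  }
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, as_plain))
  }
  if (is.matrix(x)) return(x)
  unclass(x)
}

#' Write a pipeline product to JSON or CSV
#'
#' Any pipeline object (criteria set, suitability summary, fit, or the
#' whole pipeline result) round-trips its numeric fields at full
#' precision. Data frames written to a `.csv` path use one row per
#' record; everything else (and any object on a `.json` path) is written
#' as JSON.
#'
#' @param results A pipeline product.
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (is.null(results) ||
      (is.data.frame(results) && nrow(results) == 0) ||
      (!is.data.frame(results) && is.list(results) &&
       length(results) == 0)) {
    warning("writing an empty report to ", path, call. = FALSE)
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (!is.data.frame(results)) {
      stop("CSV output requires a data frame; got ",
           class(results)[1], call. = FALSE)
    }
    utils::write.csv(as_plain(results), path, row.names = FALSE)
  } else {
    jsonlite::write_json(as_plain(results), path, auto_unbox = TRUE,
                         digits = NA, na = "null", matrix = "rowmajor")
  }
  invisible(path)
}
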