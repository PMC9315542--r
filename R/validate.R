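#' Suitability classification of paired samples against the criteria
#'
#' Cross-classifies each site's soil Cd (against its band's criterion at
#' one protection level) and grain Cd (against the FQS):
#' A (unsuitable) soil > SC and rice > FQS; B (false negative) soil <= SC,
#' rice > FQS; C (suitable) soil <= SC, rice <= FQS; D (false positive)
#' soil > SC, rice <= FQS. Soil and rice comparisons both use `<=`.
#'
#' @param samples A `paired_samples` tibble.
#' @param criteria A `criteria_set`.
#' @param protection Protection level selecting the criteria row
#'   (default 0.5, the moderate-risk SC_50).
#' @param fqs Food quality standard, mg kg-1 DW (defaults to the value
#'   stored in `criteria`).
#' @return Object of class `suitability_summary`: list with `summary`
#'   (tibble: band, n, counts and fractions of A-D, sc_used) and
#'   `details` (per-site categories).
#' @export
classify_suitability <- function(samples, criteria, protection = 0.5,
                                 fqs = attr(criteria, "fqs")) {
  sub <- criteria[criteria$protection == protection, ]
  if (!nrow(sub)) {
    stop("criteria do not contain protection level ", protection,
         call. = FALSE)
  }
  sc_by_band <- stats::setNames(sub$sc, sub$band)
  band <- as.character(samples$band)
  if (any(!band %in% names(sc_by_band))) {
    stop("no criteria value for band(s): ",
         toString(setdiff(unique(band), names(sc_by_band))), call. = FALSE)
  }
  sc <- unname(sc_by_band[band])
  soil_over <- samples$cd_soil > sc
  rice_over <- samples$cd_rice > fqs
  category <- ifelse(soil_over & rice_over, "A",
              ifelse(!soil_over & rice_over, "B",
              ifelse(!soil_over & !rice_over, "C", "D")))

  details <- tibble::tibble(site_id = samples$site_id, band = band,
                            sc = sc, category = category)
  rows <- lapply(band_levels(), function(b) {
    in_b <- band == b
    n <- sum(in_b)
    counts <- vapply(c("A", "B", "C", "D"),
                     function(k) sum(category[in_b] == k), integer(1))
    tibble::tibble(
      band = b, n = n,
      A = counts[["A"]], B = counts[["B"]], C = counts[["C"]],
      D = counts[["D"]],
      frac_A = if (n) counts[["A"]] / n else NA_real_,
      frac_B = if (n) counts[["B"]] / n else NA_real_,
      frac_C = if (n) counts[["C"]] / n else NA_real_,
      frac_D = if (n) counts[["D"]] / n else NA_real_,
      sc_used = if (b %in% names(sc_by_band)) sc_by_band[[b]] else NA_real_
    )
  })
  structure(list(summary = do.call(rbind, rows), details = details,
                 protection = protection, fqs = fqs),
            class = "suitability_summary")
}

#' Exceeding-factor safety assessment of rice grain
#'
#' The exceeding factor `E = Cd_rice / FQS` classifies each site as safe
#' (`E <= 1`), moderate (`1 < E <= 2`) or severe (`E > 2`). When
#' `criteria` are supplied, the report adds the conditional assessment
#' among sites whose soil Cd exceeds the criterion at `protection`
#' (used to validate SC_95: the fraction of grain above the FQS and the
#' fraction severe among soils above the criterion).
#'
#' @param samples A `paired_samples` tibble.
#' @param fqs Food quality standard, mg kg-1 DW.
#' @param criteria Optional `criteria_set` for the conditional assessment.
#' @param protection Protection level of the conditioning criterion
#'   (default 0.05, i.e. SC_95).
#' @return Object of class `exceedance_report`: list with `records`
#'   (site_id, band, e, category), `band_fractions`, and when `criteria`
#'   are given `conditional` (n_above, frac_rice_over_fqs, frac_severe,
#'   unconditional_frac_severe).
#' @export
exceeding_factors <- function(samples, fqs, criteria = NULL,
                              protection = 0.05) {
  stopifnot(fqs > 0)
  e <- samples$cd_rice / fqs
  category <- ifelse(e <= 1, "safe", ifelse(e <= 2, "moderate", "severe"))
  records <- tibble::tibble(site_id = samples$site_id,
                            band = as.character(samples$band),
                            e = e, category = category)
  band_fractions <- do.call(rbind, lapply(band_levels(), function(b) {
    in_b <- records$band == b
    n <- sum(in_b)
    tibble::tibble(
      band = b, n = n,
      frac_safe = if (n) mean(category[in_b] == "safe") else NA_real_,
      frac_moderate = if (n) mean(category[in_b] == "moderate") else NA_real_,
      frac_severe = if (n) mean(category[in_b] == "severe") else NA_real_
    )
  }))
  out <- list(records = records, band_fractions = band_fractions, fqs = fqs)
  if (!is.null(criteria)) {
    sub <- criteria[criteria$protection == protection, ]
    if (!nrow(sub)) {
      stop("criteria do not contain protection level ", protection,
           call. = FALSE)
    }
    sc <- stats::setNames(sub$sc, sub$band)[as.character(samples$band)]
    above <- samples$cd_soil > sc
    out$conditional <- tibble::tibble(
      protection = protection,
      n_above = sum(above),
      frac_rice_over_fqs = if (any(above)) mean(samples$cd_rice[above] > fqs)
                           else NA_real_,
      frac_severe = if (any(above)) mean(category[above] == "severe")
                    else NA_real_,
      unconditional_frac_severe = mean(category == "severe")
    )
  }
  class(out) <- "exceedance_report"
  out
}

#' Spearman rank-correlation report
#'
#' Descriptive pairwise-complete Spearman correlations among soil Cd,
#' grain Cd, BCF, pH, SOM and clay. Columns with fewer than 3 complete
#' pairs or no variation yield `NA`.
#'
#' @param samples A `paired_samples` tibble.
#' @return Symmetric correlation matrix.
#' @export
spearman_report <- function(samples) {
  d <- as.data.frame(samples)[, c("cd_soil", "cd_rice", "bcf", "ph",
                                  "som", "clay")]
  d <- d[, vapply(d, function(x) any(is.finite(x)), logical(1)),
         drop = FALSE]
  suppressWarnings(
    stats::cor(d, method = "spearman", use = "pairwise.complete.obs")
  )
}

#' @export
print.suitability_summary <- function(x, ...) {
  cat(sprintf("Suitability classification at protection %.2f (FQS %.3g)\n",
              x$protection, x$fqs))
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
print.exceedance_report <- function(x, ...) {
  cat("Exceeding-factor assessment (FQS", x$fqs, "mg/kg)\n")
  print(as.data.frame(x$band_fractions), digits = 3, row.names = FALSE)
  if (!is.null(x$conditional)) {
    cat("Conditional on soil above the criterion:\n")
    print(as.data.frame(x$conditional), digits = 3, row.names = FALSE)
  }
  invisible(x)
}
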