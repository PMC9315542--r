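#' Combine SPT and SSD thresholds into final soil criteria
#'
#' Applies the conservative minimum rule: the criterion for each
#' (pH band, protection level) cell is the smaller of the
#' transfer-model-derived and the SSD-derived threshold, with the winning
#' source recorded (ties go to `ssd`). A cell covered by a single source
#' uses that source and is flagged. The within-band ordering
#' `SC_5 <= SC_50 <= SC_95` is checked and any violating cell raises an
#' error rather than being silently reordered.
#'
#' @param spt_thresholds Tibble from [spt_band_thresholds()].
#' @param ssd_thresholds Tibble from [ssd_band_thresholds()].
#' @param config A `pipeline_config`.
#' @return A tibble of class `criteria_set` with columns `band`,
#'   `protection`, `label`, `spt`, `ssd`, `sc`, `source`,
#'   `single_source`; attribute `fqs` and `config` carry provenance.
#' @export
derive_criteria <- function(spt_thresholds, ssd_thresholds,
                            config = pipeline_config()) {
  key <- function(d) paste(d$band, d$protection)
  bands <- band_levels()
  rows <- list()
  for (band in bands) {
    for (p in config$protection_levels) {
      k <- paste(band, p)
      spt_v <- if (!is.null(spt_thresholds)) {
        v <- spt_thresholds$sc[key(spt_thresholds) == k]
        if (length(v)) v[1] else NA_real_
      } else NA_real_
      ssd_v <- if (!is.null(ssd_thresholds)) {
        v <- ssd_thresholds$sc[key(ssd_thresholds) == k]
        if (length(v)) v[1] else NA_real_
      } else NA_real_
      if (is.na(spt_v) && is.na(ssd_v)) {
        stop("no threshold from either source for band '", band,
             "' at protection ", p, call. = FALSE)
      }
      sc <- min(spt_v, ssd_v, na.rm = TRUE)
      source <- if (is.na(ssd_v)) "spt"
                else if (is.na(spt_v)) "ssd"
                else if (ssd_v <= spt_v) "ssd" else "spt"
      rows[[length(rows) + 1]] <- tibble::tibble(
        band = band, protection = p, label = sc_label(p),
        spt = spt_v, ssd = ssd_v, sc = sc, source = source,
        single_source = is.na(spt_v) || is.na(ssd_v)
      )
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$single_source)) {
    warning("single-source criteria cells: ",
            toString(paste(out$band, out$label)[out$single_source]),
            call. = FALSE)
  }
  # SC_5 <= SC_50 <= SC_95: sc must be non-increasing in protection
  for (band in bands) {
    sub <- out[out$band == band, ]
    sub <- sub[order(-sub$protection), ]
    if (is.unsorted(sub$sc)) {
      stop("criteria ordering violated in band '", band, "': ",
           paste(sub$label, signif(sub$sc, 4), collapse = ", "),
           call. = FALSE)
    }
  }
  class(out) <- c("criteria_set", class(out))
  attr(out, "fqs") <- config$fqs
  attr(out, "config") <- unclass(config)
  out
}

#' Compare derived criteria to a regulatory reference table
#'
#' Ratios each band's criterion at one protection level against a
#' user-supplied regulatory value (for example the GB 15618-2018 risk
#' screening values against SC_5, or the intervention values against
#' SC_95). A criterion below the reference is `stricter`; above,
#' `looser`; equal, `equal`.
#'
#' @param criteria A `criteria_set`.
#' @param reference Named numeric vector, one value per pH band
#'   (mg kg-1).
#' @param protection Protection level of the criteria row to compare.
#' @return Tibble with `band`, `label`, `sc`, `reference`, `ratio`,
#'   `direction`.
#' @export
compare_to_reference <- function(criteria, reference, protection) {
  sub <- criteria[criteria$protection == protection, ]
  if (!nrow(sub)) {
    stop("criteria do not contain protection level ", protection,
         call. = FALSE)
  }
  missing_bands <- setdiff(sub$band, names(reference))
  if (length(missing_bands)) {
    stop("reference table lacks band(s): ", toString(missing_bands),
         call. = FALSE)
  }
  ref <- as.numeric(reference[sub$band])
  tibble::tibble(
    band = sub$band, label = sub$label, sc = sub$sc, reference = ref,
    ratio = sub$sc / ref,
    direction = ifelse(sub$sc < ref, "stricter",
                       ifelse(sub$sc > ref, "looser", "equal"))
  )
}

#' @export
print.criteria_set <- function(x, ...) {
  cat("Soil Cd criteria (mg/kg DW), FQS =", attr(x, "fqs"), "mg/kg\n")
  wide <- stats::reshape(
    as.data.frame(x)[, c("band", "label", "sc")],
    idvar = "label", timevar = "band", direction = "wide"
  )
  names(wide) <- sub("^sc\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}
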