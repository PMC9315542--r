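#' Soil pH bands of the Chinese agricultural soil standard
#'
#' The four pH bands of GB 15618-2018 used throughout the pipeline:
#' highly acidic (pH <= 5.5), acidic (5.5 < pH <= 6.5), neutral
#' (6.5 < pH <= 7.5) and alkaline (pH > 7.5). Boundaries are
#' upper-inclusive, and the four bands partition the pH axis.
#'
#' @return A tibble with columns `label` (factor in band order), `lower`
#'   and `upper` (band limits, pH units; `-Inf`/`Inf` for the open ends).
#' @export
#' @examples
#' ph_bands()
ph_bands <- function() {
  tibble::tibble(
    label = factor(band_levels(), levels = band_levels()),
    lower = c(-Inf, 5.5, 6.5, 7.5),
    upper = c(5.5, 6.5, 7.5, Inf)
  )
}

band_levels <- function() c("highly_acidic", "acidic", "neutral", "alkaline")

#' Assign soil pH values to standard pH bands
#'
#' @param ph Numeric vector of soil pH values, each in (0, 14).
#' @return Factor with levels `highly_acidic`, `acidic`, `neutral`,
#'   `alkaline`. Band boundaries are upper-inclusive: pH 5.5 is
#'   `highly_acidic`, 6.5 `acidic`, 7.5 `neutral`.
#' @export
#' @examples
#' assign_band(c(5.5, 5.50001, 8.93))
assign_band <- function(ph) {
  stopifnot(is.numeric(ph))
  bad <- !is.na(ph) & (ph <= 0 | ph >= 14)
  if (any(bad)) {
    stop("pH values outside (0, 14): ", toString(ph[bad]), call. = FALSE)
  }
  cut(ph, breaks = c(-Inf, 5.5, 6.5, 7.5, Inf), labels = band_levels(),
      right = TRUE)
}
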