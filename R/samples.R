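#' Construct a validated table of soil-rice paired samples
#'
#' Checks the row-level invariants (positive Cd concentrations so that log
#' transforms are defined, pH in (0, 14)), computes the bioconcentration
#' factor BCF = Cd_rice / Cd_soil and assigns each site to its GB 15618-2018
#' pH band. Rows violating an invariant are dropped with a warning that
#' names them.
#'
#' @param x A data frame with columns `cd_soil`, `cd_rice`, `ph`
#'   (mg kg-1 DW, mg kg-1 DW, pH units) and optionally `site_id`,
#'   `som` (g kg-1) and `clay` (%).
#' @return A tibble of class `paired_samples` with columns `site_id`,
#'   `cd_soil`, `cd_rice`, `ph`, `som`, `clay`, `bcf`, `band`. Row indices
#'   of rejected input rows are attached as attribute `rejected`.
#' @export
as_paired_samples <- function(x) {
  x <- as.data.frame(x)
  required <- c("cd_soil", "cd_rice", "ph")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", toString(missing_cols), call. = FALSE)
  }
  n <- nrow(x)
  if (is.null(x$site_id)) x$site_id <- sprintf("S%04d", seq_len(n))
  if (is.null(x$som)) x$som <- NA_real_
  if (is.null(x$clay)) x$clay <- NA_real_

  bad <- !is.finite(x$cd_soil) | x$cd_soil <= 0 |
    !is.finite(x$cd_rice) | x$cd_rice <= 0 |
    !is.finite(x$ph) | x$ph <= 0 | x$ph >= 14
  if (any(bad)) {
    warning("rejected ", sum(bad), " row(s) violating sample invariants: ",
            toString(which(bad)), call. = FALSE)
  }
  keep <- x[!bad, , drop = FALSE]
  out <- tibble::tibble(
    site_id = as.character(keep$site_id),
    cd_soil = as.numeric(keep$cd_soil),
    cd_rice = as.numeric(keep$cd_rice),
    ph      = as.numeric(keep$ph),
    som     = as.numeric(keep$som),
    clay    = as.numeric(keep$clay)
  )
  out$bcf <- out$cd_rice / out$cd_soil
  out$band <- assign_band(out$ph)
  class(out) <- c("paired_samples", class(out))
  attr(out, "rejected") <- which(bad)
  out
}

# canonical CSV header -> internal column name
canonical_schema <- function() {
  c(site_id = "site_id", cd_soil = "cd_soil_mgkg", cd_rice = "cd_rice_mgkg",
    ph = "ph", som = "som_gkg", clay = "clay_pct")
}

#' Read soil-rice paired samples from a CSV file
#'
#' The canonical header is `site_id, cd_soil_mgkg, cd_rice_mgkg, ph,
#' som_gkg, clay_pct`; files with other headers are supported through
#' `schema`, a named character vector mapping internal names
#' (`cd_soil`, `cd_rice`, `ph`, optionally `site_id`, `som`, `clay`) to
#' the file's column names. Internal names used directly as headers are
#' also accepted.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector overriding the canonical
#'   column mapping.
#' @return A `paired_samples` tibble (see [as_paired_samples()]).
#' @export
read_samples <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  map <- canonical_schema()
  if (!is.null(schema)) map[names(schema)] <- schema

  out <- list()
  for (internal in names(map)) {
    col <- if (map[[internal]] %in% names(raw)) map[[internal]]
           else if (internal %in% names(raw)) internal
           else NA_character_
    if (!is.na(col)) out[[internal]] <- raw[[col]]
  }
  required <- c("cd_soil", "cd_rice", "ph")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols)) {
    stop("input table lacks required column(s): ",
         toString(map[missing_cols]), call. = FALSE)
  }
  as_paired_samples(as.data.frame(out, stringsAsFactors = FALSE))
}

#' Write paired samples to the canonical CSV layout
#'
#' Inverse of [read_samples()]: `read_samples(write_samples(x, f))` returns
#' a table equal to `x` on all measurement columns.
#'
#' @param samples A `paired_samples` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  df <- data.frame(
    site_id = samples$site_id,
    cd_soil_mgkg = samples$cd_soil,
    cd_rice_mgkg = samples$cd_rice,
    ph = samples$ph,
    som_gkg = samples$som,
    clay_pct = samples$clay
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.paired_samples <- function(x, ...) {
  cat("Soil-rice paired samples: ", nrow(x), " sites\n", sep = "")
  cat("  pH bands: ",
      paste(sprintf("%s=%d", levels(x$band), tabulate(x$band, 4)),
            collapse = ", "), "\n", sep = "")
  NextMethod()
}
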