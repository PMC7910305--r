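#' Compute the Enhanced Vegetation Index from band reflectances
#'
#' EVI is computed from blue, red, and near-infrared surface reflectance with
#' the standard Landsat coefficients:
#' \deqn{EVI = G \frac{NIR - Red}{NIR + C_1 Red - C_2 Blue + L}}
#' with gain \eqn{G = 2.5}, aerosol coefficients \eqn{C_1 = 6},
#' \eqn{C_2 = 7.5}, and canopy background term \eqn{L = 1}.
#'
#' Observations whose denominator magnitude falls below \code{tol} are
#' undefined and returned as \code{NA} with a warning: the index is a ratio
#' and carries no information there.
#'
#' @param nir,red,blue numeric vectors of surface reflectance in [0, 1]
#'   (recycled to a common length).
#' @param tol denominator magnitude below which EVI is undefined.
#' @return numeric vector of EVI values; undefined observations are `NA`.
#' @examples
#' compute_evi(nir = 0.5, red = 0.1, blue = 0.05)
#' compute_evi(nir = c(0.05, 0.3), red = c(0.2, 0.1), blue = 0)
#' @export
compute_evi <- function(nir, red, blue, tol = 1e-6) {
  n <- max(length(nir), length(red), length(blue))
  nir <- rep_len(as.numeric(nir), n)
  red <- rep_len(as.numeric(red), n)
  blue <- rep_len(as.numeric(blue), n)
  bad <- !is.finite(nir) | !is.finite(red) | !is.finite(blue) |
    nir < 0 | nir > 1 | red < 0 | red > 1 | blue < 0 | blue > 1
  if (any(bad)) {
    stop("reflectances must be finite and within [0, 1]")
  }
  den <- nir + 6 * red - 7.5 * blue + 1
  evi <- 2.5 * (nir - red) / den
  undef <- abs(den) < tol
  if (any(undef)) {
    evi[undef] <- NA_real_
    warning(sprintf("%d observation(s) with |denominator| < %g dropped as undefined EVI",
                    sum(undef), tol))
  }
  evi
}

#' Construct an EVI time series
#'
#' An `evi_series` is the pipeline's central container: dated EVI
#' observations for one site or plot. Dates are sorted strictly increasing;
#' observations at duplicated dates are averaged. Values outside [-1, 1] are
#' flagged invalid (habitat classes live inside (-1, 0.325)) and excluded,
#' with the exclusion count retained.
#'
#' @param id site or plot identifier.
#' @param date vector coercible to `Date`.
#' @param evi numeric EVI values.
#' @return an object of class `evi_series` with elements `id`, `date`,
#'   `evi`, and `n_excluded`.
#' @export
evi_series <- function(id, date, evi) {
  date <- as.Date(date)
  evi <- as.numeric(evi)
  if (length(date) != length(evi)) stop("date and evi lengths differ")
  keep <- is.finite(evi) & abs(evi) <= 1 & !is.na(date)
  n_excluded <- sum(!keep)
  date <- date[keep]
  evi <- evi[keep]
  if (anyDuplicated(date)) {
    evi <- as.numeric(tapply(evi, as.integer(date), mean))
    date <- as.Date(sort(unique(as.integer(date))), origin = "1970-01-01")
    message(sprintf("series '%s': duplicate dates averaged", id))
  } else {
    o <- order(date)
    date <- date[o]
    evi <- evi[o]
  }
  structure(list(id = as.character(id), date = date, evi = evi,
                 n_excluded = n_excluded),
            class = "evi_series")
}

#' @export
print.evi_series <- function(x, ...) {
  cat(sprintf("EVI series '%s': %d observations", x$id, length(x$evi)))
  if (length(x$evi)) {
    cat(sprintf(" (%s to %s), range [%.3f, %.3f]",
                format(min(x$date)), format(max(x$date)),
                min(x$evi), max(x$evi)))
  }
  cat("\n")
  if (x$n_excluded > 0)
    cat(sprintf("  %d invalid observation(s) excluded\n", x$n_excluded))
  invisible(x)
}

#' @export
length.evi_series <- function(x) length(x$evi)

#' Seasonal average of an EVI series
#'
#' Arithmetic mean of the observations falling in the given calendar year
#' and months — the nesting-season summary (March-April by default, the
#' window over which scenes are averaged per plot-year).
#'
#' @param series an [evi_series()].
#' @param year calendar year.
#' @param months integer months to include; default `c(3, 4)`.
#' @return the mean EVI, or `NA` when no observation falls in the window.
#' @export
seasonal_average <- function(series, year, months = c(3L, 4L)) {
  stopifnot(inherits(series, "evi_series"), length(months) >= 1)
  lt <- as.POSIXlt(series$date)
  sel <- (lt$year + 1900L) == year & (lt$mon + 1L) %in% as.integer(months)
  if (!any(sel)) return(NA_real_)
  mean(series$evi[sel])
}

#' Build an EVI time series from a band observation table
#'
#' Rows carry per-scene reflectances for one site or plot; EVI is computed
#' per row, undefined observations are dropped (counted), duplicate dates
#' averaged, and the result sorted chronologically.
#'
#' @param band_table data frame with columns `id`, `date`, `blue`, `red`,
#'   `nir`.
#' @param id identifier to extract; all matching rows are used.
#' @return an [evi_series()].
#' @export
build_timeseries <- function(band_table, id) {
  stopifnot(all(c("id", "date", "blue", "red", "nir") %in% names(band_table)))
  rows <- band_table[band_table$id == id, , drop = FALSE]
  if (nrow(rows) == 0) {
    return(evi_series(id, as.Date(character(0)), numeric(0)))
  }
  evi <- suppressWarnings(
    compute_evi(rows$nir, rows$red, rows$blue)
  )
  evi_series(id, rows$date, evi)
}

#' Read an EVI series table written by the generator
#'
#' @param path CSV with columns `site`, `date`, `evi`.
#' @return a named list of [evi_series()] objects, one per site.
#' @export
read_evi_series_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("site", "date", "evi") %in% names(d)))
  sites <- unique(d$site)
  out <- lapply(sites, function(s) {
    r <- d[d$site == s, ]
    evi_series(s, r$date, r$evi)
  })
  names(out) <- sites
  out
}
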