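#' Parse a nest-site usage table
#'
#' Entries follow the nest-table legend: an integer is a nest count, `"+"`
#' is nesting observed but not counted, `"0"` is a vacant site, and `"-"`
#' (or the typographic dash) means no subsequent nesting — the site is
#' recorded as unused that year.
#'
#' @param rows data frame with columns `site`, `bank_type` (`"RB"` river
#'   bank or `"SB"` mid-river sand bar), `year`, `entry`.
#' @return an object of class `nest_table`: the typed records plus the
#'   derived columns `count` (integer or `NA`), `nesting` (logical:
#'   nesting occurred), `used` (logical: site in use that year).
#' @export
parse_nest_table <- function(rows) {
  stopifnot(all(c("site", "bank_type", "year", "entry") %in% names(rows)))
  entry <- trimws(as.character(rows$entry))
  entry[entry %in% c("–", "—")] <- "-"  # en/em dash
  legal <- grepl("^[0-9]+$", entry) | entry %in% c("+", "-")
  if (any(!legal)) {
    bad <- which(!legal)[1]
    stop(sprintf("parse error in row %d (site %s, year %s): illegal entry '%s'",
                 bad, rows$site[bad], rows$year[bad], entry[bad]))
  }
  if (anyDuplicated(paste(rows$site, rows$year)))
    stop("parse error: more than one entry per (site, year)")
  bt_per_site <- tapply(rows$bank_type, rows$site,
                        function(v) length(unique(v)))
  if (any(bt_per_site > 1))
    stop("parse error: bank type must be constant per site")
  count <- suppressWarnings(as.integer(entry))
  nesting <- entry == "+" | (!is.na(count) & count > 0)
  used <- entry != "-"
  structure(data.frame(
    site = as.character(rows$site),
    bank_type = as.character(rows$bank_type),
    year = as.integer(rows$year),
    entry = entry, count = count, nesting = nesting, used = used,
    stringsAsFactors = FALSE, row.names = NULL
  ), class = c("nest_table", "data.frame"))
}

#' Read a nest table from CSV
#'
#' @param path CSV with columns `site`, `bank_type`, `year`, `entry`.
#' @return a [parse_nest_table()] result.
#' @export
read_nest_table_csv <- function(path) {
  parse_nest_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                   colClasses = "character"))
}

#' Write a nest table back to CSV
#'
#' Writes the four raw columns, so parse - write - parse round-trips.
#'
#' @param table a `nest_table`.
#' @param path output path.
#' @export
write_nest_table_csv <- function(table, path) {
  utils::write.csv(table[, c("site", "bank_type", "year", "entry")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Yearly summary of a nest table
#'
#' The yearly total is the sum of integer entries, but only when no site
#' that year carries an uncounted `"+"` — otherwise the total is undefined
#' (`NA`) and the partial sum is reported separately. Active sites are
#' those with `"+"` or a positive count.
#'
#' @param table a `nest_table`.
#' @param year year present in the table.
#' @return list with `year`, `total` (or `NA`), `partial_total`,
#'   `active_sites`, `max_count`, `max_site`.
#' @export
summarize_year <- function(table, year) {
  stopifnot(inherits(table, "nest_table"))
  rows <- table[table$year == year, , drop = FALSE]
  if (nrow(rows) == 0) stop("year ", year, " not present in table")
  has_plus <- any(rows$entry == "+")
  partial <- sum(rows$count, na.rm = TRUE)
  total <- if (has_plus) NA_integer_ else as.integer(partial)
  active <- sum(rows$nesting)
  counted <- rows[!is.na(rows$count) & rows$count > 0, , drop = FALSE]
  max_count <- if (nrow(counted)) max(counted$count) else NA_integer_
  max_site <- if (nrow(counted)) counted$site[which.max(counted$count)]
              else NA_character_
  list(year = as.integer(year), total = total,
       partial_total = as.integer(partial),
       active_sites = as.integer(active),
       max_count = max_count, max_site = max_site)
}

#' Percent decline between two values
#'
#' `100 * (v_start - v_end) / v_start`, reported raw and rounded to the
#' nearest integer.
#'
#' @param v_start,v_end non-negative numbers; `v_start` must be positive.
#' @return list with `raw` and `rounded`.
#' @examples
#' percent_decline(35, 19)  # 45.7..., rounds to 46
#' @export
percent_decline <- function(v_start, v_end) {
  if (!is.finite(v_start) || v_start <= 0)
    stop("percent decline undefined for v_start <= 0")
  raw <- 100 * (v_start - v_end) / v_start
  list(raw = raw, rounded = as.integer(round(raw)))
}

#' Path to the packaged nest-site usage fixture
#'
#' A plain-text transcription of the 2015-2019 nest-site usage table for
#' the eight Girwa River sites (N1-N8), with the published yearly totals
#' in a companion file (`table2_totals.csv`) — the 2016 total is not
#' recomputable from per-site entries because that year's nesting was
#' recorded but not counted per site.
#'
#' @param totals if `TRUE`, return the path of the published-totals file.
#' @return file path.
#' @export
table2_path <- function(totals = FALSE) {
  system.file("extdata",
              if (totals) "table2_totals.csv" else "table2.csv",
              package = "rivershift", mustWork = TRUE)
}
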