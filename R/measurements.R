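.measurement_cols <- c("instrument_id", "sample_id", "side",
                       "critical_extent_um", "necrosis_extent_um",
                       "frontier_temp_C")

#' Validate a table of per-sample zone measurements
#'
#' A measurement table holds, per sealing event and per side of the branch
#' band, the lateral extent of the >50 degC critical zone, the extent of the
#' histological necrosis zone, and the frontier temperature (the temperature
#' read from the thermogram at the peripheral margin of the necrosis zone).
#'
#' Required columns: `instrument_id`, `sample_id`, `side` (`"above"` or
#' `"below"`), `critical_extent_um`, `necrosis_extent_um`, `frontier_temp_C`.
#' Necrosis and frontier values may be `NA` (e.g. thermography-only rows);
#' additional columns are carried through unchanged.
#'
#' Enforced invariants: extents are non-negative; the necrosis zone lies
#' inside the critical zone (`necrosis <= critical` whenever both are present
#' and positive); the key `(instrument_id, sample_id, side)` is unique.
#'
#' @param x A data frame with at least the required columns.
#' @return `x`, validated, with class `measurement_table` prepended.
#' @export
measurement_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing <- setdiff(.measurement_cols, names(x))
  if (length(missing)) {
    stop(sprintf("measurement table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x$instrument_id <- as.character(x$instrument_id)
  x$side <- as.character(x$side)
  if (nrow(x) > 0L) {
    bad_side <- which(!x$side %in% c("above", "below"))
    if (length(bad_side)) {
      stop(sprintf("row %d: 'side' must be \"above\" or \"below\" (got \"%s\")",
                   bad_side[1], x$side[bad_side[1]]), call. = FALSE)
    }
    for (col in c("critical_extent_um", "necrosis_extent_um",
                  "frontier_temp_C")) {
      x[[col]] <- as.numeric(x[[col]])
    }
    neg <- which(x$critical_extent_um < 0 | x$necrosis_extent_um < 0)
    if (length(neg)) {
      stop(sprintf("row %d (%s, sample %s, %s): extents must be >= 0",
                   neg[1], x$instrument_id[neg[1]], x$sample_id[neg[1]],
                   x$side[neg[1]]), call. = FALSE)
    }
    viol <- which(!is.na(x$necrosis_extent_um) & !is.na(x$critical_extent_um) &
                  x$necrosis_extent_um > 0 & x$critical_extent_um > 0 &
                  x$necrosis_extent_um > x$critical_extent_um)
    if (length(viol)) {
      stop(sprintf(paste0("row %d (%s, sample %s, %s): necrosis extent (%g um) ",
                          "exceeds critical extent (%g um); the necrosis zone ",
                          "must lie inside the >50 degC zone"),
                   viol[1], x$instrument_id[viol[1]], x$sample_id[viol[1]],
                   x$side[viol[1]], x$necrosis_extent_um[viol[1]],
                   x$critical_extent_um[viol[1]]), call. = FALSE)
    }
    key <- paste(x$instrument_id, x$sample_id, x$side, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup)) {
      stop(sprintf("duplicate measurement key: (%s, sample %s, %s)",
                   x$instrument_id[dup[1]], x$sample_id[dup[1]],
                   x$side[dup[1]]), call. = FALSE)
    }
  }
  class(x) <- unique(c("measurement_table", class(x)))
  x
}

#' Read a measurement table from TSV
#'
#' Expects a tab-separated file whose header names (at least) the six
#' required columns of [measurement_table()]. A file with only a header row
#' yields an empty, valid table. Numbers use the '.' decimal separator.
#'
#' @param path Path to a TSV file.
#' @return A [measurement_table()].
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  measurement_table(df)
}

#' Write a measurement table to TSV
#'
#' Columns are written in the canonical order (the six required columns
#' first, any extra columns after), tab-separated, '.' decimal separator, no
#' quoting and no row names.
#'
#' @param x A [measurement_table()] (or coercible data frame).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_measurements <- function(x, path) {
  x <- measurement_table(x)
  ord <- c(.measurement_cols, setdiff(names(x), .measurement_cols))
  utils::write.table(x[, ord, drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The published per-sample reference dataset
#'
#' Returns the complete per-sample table of the published ex vivo porcine
#' carotid sealing study that this package reanalyses: 15 sealing events per
#' instrument (marSeal 5 plus and BiCision 5 mm), each measured above and
#' below the instrument branches, i.e. 60 rows of critical-zone extent (um),
#' necrosis-zone extent (um) and necrosis frontier temperature (degC). The
#' extra column `rilate_printed` carries the per-sample RILATE index exactly
#' as printed in the source table (1 decimal); it is retained for regression
#' comparison only - recompute indices from the extent columns with
#' [rilate()].
#'
#' @return A [measurement_table()] with 60 rows and a `rilate_printed` column.
#' @examples
#' tab <- table1_fixture()
#' nrow(tab)
#' summarize_group(tab, "marSeal", "above")
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_measurements.tsv",
                      package = "rilate", mustWork = TRUE)
  read_measurements(path)
}
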