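# Published group-level values of the reference study, used only for
# side-by-side regression reporting. Group means/SDs are re-derivable from
# the per-sample fixture; the p-values are the study's printed test results.
.published_groups <- data.frame(
  instrument_id = c("marSeal", "marSeal", "BiCision", "BiCision"),
  side = c("above", "below", "above", "below"),
  mean_critical_um = c(2315, 1700, 2032, 1182),
  sd_critical_um = c(509.2, 331.3, 592.4, 386.9),
  mean_necrosis_um = c(412.5, 426.7, 642.6, 645.3),
  sd_necrosis_um = c(79.0, 100.7, 158.2, 111.9),
  mean_frontier_c = c(64.93, 63.42, 60.42, 55.28),
  sd_frontier_c = c(4.1, 3.38, 4.2, 4.1),
  group_rilate = c(17.8, 25.1, 31.62, 54.59),
  stringsAsFactors = FALSE
)

.published_pvalues <- data.frame(
  instrument_id = rep(c("marSeal", "BiCision"), each = 4L),
  quantity = rep(c("critical_extent", "necrosis_extent",
                   "frontier_temperature", "sample_rilate"), 2L),
  printed_p = c("0.0006", "0.98", "0.28", "0.05",
                "<0.0001", "0.9", "0.002", "<0.0001"),
  printed_significant = c(TRUE, FALSE, FALSE, TRUE,
                          TRUE, FALSE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

# Agreement of a computed p with a printed one: at the printed precision, or
# within 15 % relative; "<bound" strings require the computed value to meet
# the bound.
.p_agrees <- function(computed, printed) {
  if (startsWith(printed, "<")) {
    return(computed < as.numeric(sub("^<", "", printed)))
  }
  target <- as.numeric(printed)
  digits <- nchar(sub("^[^.]*\\.?", "", printed))
  if (round(computed, digits) == target) return(TRUE)
  abs(computed - target) / target <= 0.15
}

#' Run the eight above-versus-below comparisons of the reference study
#'
#' For each instrument in the table, compares the samples above versus below
#' the branch band with [mann_whitney_u()] for four quantities, in this fixed
#' order: critical-zone extent, necrosis-zone extent, frontier temperature,
#' and the per-sample RILATE index (recomputed at full precision from the
#' extent columns, not taken from any printed index column).
#'
#' When the table contains the instruments of the reference dataset, each
#' result is tagged with the study's published p-value and significance call,
#' an `agrees_printed` flag (agreement at printed precision or within 15 %
#' relative; for bounds such as `<0.0001`, meeting the bound), and a
#' `borderline` flag for the one comparison whose published p equals the 0.05
#' significance level exactly, where "significant" versus "at the boundary"
#' cannot be distinguished from the printed value. Disagreements are
#' reported, never hidden: the known ones are discussed in the package
#' vignette.
#'
#' @param table A [measurement_table()] containing both sides for each
#'   instrument.
#' @param alpha Significance level (default 0.05).
#' @return A data frame with one row per comparison: `instrument_id`,
#'   `quantity`, `n_above`, `n_below`, `U`, `p_value`, `method`, `ties`,
#'   `significant`, and - where published references exist - `printed_p`,
#'   `printed_significant`, `agrees_printed`, `borderline`.
#' @examples
#' run_study_comparisons(table1_fixture())
#' @export
run_study_comparisons <- function(table, alpha = 0.05) {
  table <- measurement_table(table)
  quantities <- c(critical_extent = "critical_extent_um",
                  necrosis_extent = "necrosis_extent_um",
                  frontier_temperature = "frontier_temp_C")
  rows <- list()
  for (ins in unique(table$instrument_id)) {
    ab <- table[table$instrument_id == ins & table$side == "above", ]
    be <- table[table$instrument_id == ins & table$side == "below", ]
    if (nrow(ab) == 0L || nrow(be) == 0L) {
      stop(sprintf("instrument '%s' must have rows on both sides", ins),
           call. = FALSE)
    }
    vals <- c(lapply(quantities, function(col) list(ab[[col]], be[[col]])),
              list(sample_rilate = list(
                rilate(ab$necrosis_extent_um, ab$critical_extent_um),
                rilate(be$necrosis_extent_um, be$critical_extent_um))))
    for (q in names(vals)) {
      res <- mann_whitney_u(vals[[q]][[1]], vals[[q]][[2]], alpha = alpha,
                            labels = paste(ins, c("above", "below")))
      rows[[length(rows) + 1L]] <- data.frame(
        instrument_id = ins, quantity = q,
        n_above = res$n1, n_below = res$n2, U = res$U,
        p_value = res$p_value, method = res$method, ties = res$ties,
        significant = res$significant, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ref <- merge(out, .published_pvalues, by = c("instrument_id", "quantity"),
               all.x = TRUE, sort = FALSE)
  # merge() reorders; restore the documented fixed order
  ord <- match(paste(out$instrument_id, out$quantity),
               paste(ref$instrument_id, ref$quantity))
  ref <- ref[ord, ]
  ref$agrees_printed <- ifelse(
    is.na(ref$printed_p), NA,
    mapply(function(p, pr) if (is.na(pr)) NA else .p_agrees(p, pr),
           ref$p_value, ref$printed_p))
  ref$borderline <- !is.na(ref$printed_p) & ref$printed_p == "0.05"
  rownames(ref) <- NULL
  ref
}

#' Recompute every published downstream number from the per-sample fixture
#'
#' Runs the whole downstream pipeline on the packaged reference dataset:
#' the four group summaries ([summarize_group()]) and the eight
#' above-versus-below tests ([run_study_comparisons()]), and lays the
#' computed values side by side with the published ones, rounded to the
#' published precision.
#'
#' @return An object of class `table1_report` with elements
#'   \describe{
#'     \item{groups}{data frame of computed group statistics (full
#'       precision);}
#'     \item{group_check}{data frame comparing computed values rounded to
#'       published precision against the published group table, with a
#'       `match` column;}
#'     \item{comparisons}{the eight-test data frame of
#'       [run_study_comparisons()].}
#'   }
#' @examples
#' rep <- reproduce_table1()
#' rep
#' @export
reproduce_table1 <- function() {
  tab <- table1_fixture()
  groups <- summarize_groups(tab)
  pub <- .published_groups
  # published rounding: extents to 4 significant digits (integer um), SDs and
  # frontier stats to 1-2 decimals as printed; match at that precision
  chk <- list()
  roundings <- list(
    mean_critical_um = 0, sd_critical_um = 1,
    mean_necrosis_um = 1, sd_necrosis_um = 1,
    mean_frontier_c = 2, sd_frontier_c = 2,
    group_rilate = NA  # published with mixed 1-2 decimals; matched adaptively
  )
  for (i in seq_len(nrow(pub))) {
    g <- groups[groups$instrument_id == pub$instrument_id[i] &
                groups$side == pub$side[i], ]
    for (col in names(roundings)) {
      published <- pub[[col]][i]
      digits <- roundings[[col]]
      if (is.na(digits)) {
        digits <- nchar(sub("^[^.]*\\.?", "", format(published)))
      }
      # frontier SDs are printed to the fewest digits shown (e.g. 4.1, 3.38)
      if (col %in% c("sd_frontier_c")) {
        digits <- nchar(sub("^[^.]*\\.?", "", format(published)))
      }
      computed <- round(g[[col]], digits)
      # the published table truncates some final digits rather than rounding
      # (e.g. an index of 54.596 printed as 54.59), so "match at published
      # precision" tolerates one unit in the last printed digit
      chk[[length(chk) + 1L]] <- data.frame(
        instrument_id = pub$instrument_id[i], side = pub$side[i],
        statistic = col, computed = computed, published = published,
        match = abs(g[[col]] - published) < 10^(-digits) + 1e-9,
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(groups = groups,
         group_check = do.call(rbind, chk),
         comparisons = run_study_comparisons(tab)),
    class = "table1_report"
  )
}

#' @export
print.table1_report <- function(x, ...) {
  n_match <- sum(x$group_check$match)
  cat(sprintf("Reference-dataset regression: %d/%d group statistics match at published precision\n",
              n_match, nrow(x$group_check)))
  mism <- x$group_check[!x$group_check$match, ]
  if (nrow(mism)) {
    cat("  mismatches:\n")
    print(mism, row.names = FALSE)
  }
  cat("\nGroup summaries (computed, full precision):\n")
  print(x$groups, row.names = FALSE, digits = 6)
  cat("\nAbove-vs-below comparisons:\n")
  cmp <- x$comparisons
  cmp$p_value <- signif(cmp$p_value, 3)
  print(cmp, row.names = FALSE)
  n_dis <- sum(!cmp$agrees_printed, na.rm = TRUE)
  if (n_dis) {
    cat(sprintf("\n%d comparison(s) disagree with the published p-value beyond printed precision / 15%%;\nsee the 'agrees_printed' column and the package vignette.\n",
                n_dis))
  }
  invisible(x)
}
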