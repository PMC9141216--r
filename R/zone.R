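#' Per-pixel peak temperature over a recording
#'
#' Reduces a frame stack to the element-wise maximum over time: each pixel's
#' peak exposure temperature. Zone extents are read from this projection
#' rather than from any single frame, because thermal tissue damage reflects
#' peak exposure and the projection is insensitive to frame rate and to when
#' during the seal the peak occurs. Appending frames that are nowhere hotter
#' than the existing maximum leaves the projection - and every extent derived
#' from it - unchanged.
#'
#' @param stack A [frame_stack()] with at least one frame.
#' @return A numeric matrix with the dimensions of one frame.
#' @export
max_projection <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  Reduce(pmax, stack$frames)
}

.transect_profile <- function(side, column, distances, temperatures) {
  structure(list(side = side, column = column,
                 distances = distances, temperatures = temperatures),
            class = "transect_profile")
}

#' @export
print.transect_profile <- function(x, ...) {
  cat(sprintf("Transect profile (%s, column %d): %d point(s)",
              x$side, x$column, length(x$distances)))
  if (length(x$distances)) {
    cat(sprintf(", 0-%g um, %.2f-%.2f degC",
                max(x$distances), min(x$temperatures), max(x$temperatures)))
  }
  cat("\n")
  invisible(x)
}

#' Extract lateral temperature transects from a projection
#'
#' Takes `n_transects` image columns, evenly spaced across the column ROI
#' (including both ROI endpoints for `n_transects >= 2`; the single transect
#' sits at the ROI centre), and turns each into two temperature-versus-
#' distance profiles: one walking upward from the branch band (rows
#' `r_top - 1, ..., 1`) and one walking downward (rows `r_bottom + 1, ...`).
#' Distance 0 is the first off-band pixel and increases in steps of one
#' pixel's worth of micrometers. The default of 15 transects mirrors the 15
#' repeated necrosis measurements per histological section in the reference
#' protocol.
#'
#' A side with no off-band rows (branch band touching the image edge) yields
#' no profiles for that side; [measure_sample()] flags such a side as absent
#' rather than reporting a zero extent.
#'
#' @param projection Numeric matrix, typically from [max_projection()].
#' @param calibration um per pixel.
#' @param branch_band Rows `c(r_top, r_bottom)` of the branch band.
#' @param column_roi Columns `c(first, last)` available for transects.
#' @param n_transects Number of transect columns (>= 1, at most the ROI
#'   width).
#' @return A list of `transect_profile` objects, the above-profiles first.
#' @export
extract_transects <- function(projection, calibration, branch_band,
                              column_roi, n_transects = 15L) {
  stopifnot(is.matrix(projection), is.numeric(projection))
  branch_band <- as.integer(branch_band)
  column_roi <- as.integer(column_roi)
  width <- column_roi[2] - column_roi[1] + 1L
  if (n_transects < 1L || n_transects > width) {
    stop(sprintf("'n_transects' must be between 1 and the ROI width (%d)",
                 width), call. = FALSE)
  }
  cols <- if (n_transects == 1L) {
    (column_roi[1] + column_roi[2]) %/% 2L
  } else {
    as.integer(round(seq(column_roi[1], column_roi[2],
                         length.out = n_transects)))
  }
  r_top <- branch_band[1]
  r_bottom <- branch_band[2]
  n_rows <- nrow(projection)
  out <- list()
  for (col in cols) {
    if (r_top > 1L) {
      rows <- seq(r_top - 1L, 1L)
      out[[length(out) + 1L]] <- .transect_profile(
        "above", col, (seq_along(rows) - 1) * calibration,
        projection[rows, col])
    }
  }
  for (col in cols) {
    if (r_bottom < n_rows) {
      rows <- seq(r_bottom + 1L, n_rows)
      out[[length(out) + 1L]] <- .transect_profile(
        "below", col, (seq_along(rows) - 1) * calibration,
        projection[rows, col])
    }
  }
  out
}

#' Lateral extent of the supra-threshold zone along one transect
#'
#' Measures the length of the contiguous run of pixels with temperature
#' strictly above `threshold_c`, starting at distance 0, with the outer
#' boundary refined by linear interpolation between the last supra-threshold
#' and the first sub-threshold pixel. Returns 0 when the first off-band pixel
#' is already at or below the threshold. The contiguous-run rule (the first
#' crossing ends the zone) makes the measurement robust to isolated distal
#' hot pixels under sensor noise; the strict `>` comparison means a pixel at
#' exactly the threshold terminates the zone.
#'
#' With `threshold_c = 50` (the default) this is the critical-zone extent;
#' called with a necrosis frontier temperature it returns the implied
#' necrosis extent, since both are crossings of the same profile.
#'
#' If the profile never crosses the threshold, the zone extends beyond the
#' imaged field: the maximum profile distance is returned with a warning.
#'
#' @param profile A `transect_profile` from [extract_transects()].
#' @param threshold_c Temperature threshold in degC (default 50, the tissue
#'   damage threshold).
#' @return Extent in um (`NA_real_` for an empty profile).
#' @examples
#' p <- rilate:::.transect_profile("above", 1L, c(0, 100, 200, 300),
#'                                 c(80, 70, 60, 40))
#' critical_extent(p)  # 250: two full steps plus an interpolated half step
#' @export
critical_extent <- function(profile, threshold_c = 50) {
  stopifnot(inherits(profile, "transect_profile"))
  tt <- profile$temperatures
  dd <- profile$distances
  n <- length(tt)
  if (n == 0L) return(NA_real_)
  if (tt[1] <= threshold_c) return(0)
  below <- which(tt <= threshold_c)
  if (length(below) == 0L) {
    warning("profile never crosses the threshold; zone is truncated by the imaged field")
    return(dd[n])
  }
  i <- below[1]
  # linear interpolation between the last supra- and first sub-threshold pixel
  dd[i - 1L] + (tt[i - 1L] - threshold_c) / (tt[i - 1L] - tt[i]) *
    (dd[i] - dd[i - 1L])
}

#' Temperature at a stated lateral distance
#'
#' Linear interpolation of a transect profile at an arbitrary distance, e.g.
#' at the histologically measured necrosis margin to obtain the frontier
#' temperature.
#'
#' @param profile A `transect_profile`.
#' @param distance_um Distance in um, within `[0, max(profile$distances)]`.
#' @return Temperature in degC.
#' @export
temperature_at <- function(profile, distance_um) {
  stopifnot(inherits(profile, "transect_profile"))
  if (length(profile$distances) == 0L) {
    stop("empty profile", call. = FALSE)
  }
  if (any(distance_um < 0 | distance_um > max(profile$distances))) {
    stop(sprintf("distance must lie within [0, %g] um",
                 max(profile$distances)), call. = FALSE)
  }
  stats::approx(profile$distances, profile$temperatures,
                xout = distance_um)$y
}

#' Measure the critical-zone extent of one sealing event
#'
#' Full measurement pipeline for one recording: max projection, transect
#' extraction, per-transect supra-threshold extents, and the per-side mean
#' extent. Per-transect values are retained for dispersion reporting.
#'
#' @param stack A [frame_stack()].
#' @param threshold_c Temperature threshold, degC (default 50).
#' @param n_transects Number of transects (default 15).
#' @return A list with elements `above` and `below`, each of class
#'   `critical_zone_result` with fields `side`, `extent_um` (mean over
#'   transects; `NA` for a degenerate side), `threshold_c`, `n_transects`,
#'   `per_transect_um`, and `degenerate` (`TRUE` when the branch band touches
#'   that image edge so the side cannot be measured).
#' @examples
#' ev <- simulate_event(event_model(noise_sd = 0), seed = 1)
#' res <- measure_sample(ev$stack)
#' res$above$extent_um            # ~ ev$truth$critical_above_um
#' @export
measure_sample <- function(stack, threshold_c = 50, n_transects = 15L) {
  stopifnot(inherits(stack, "frame_stack"))
  proj <- max_projection(stack)
  profiles <- extract_transects(proj, stack$calibration, stack$branch_band,
                                stack$column_roi, n_transects)
  one_side <- function(side) {
    ps <- Filter(function(p) p$side == side, profiles)
    if (length(ps) == 0L) {
      return(structure(list(side = side, extent_um = NA_real_,
                            threshold_c = threshold_c,
                            n_transects = 0L,
                            per_transect_um = numeric(0),
                            degenerate = TRUE),
                       class = "critical_zone_result"))
    }
    per <- vapply(ps, critical_extent, numeric(1), threshold_c = threshold_c)
    structure(list(side = side, extent_um = mean(per),
                   threshold_c = threshold_c,
                   n_transects = length(per), per_transect_um = per,
                   degenerate = FALSE),
              class = "critical_zone_result")
  }
  list(above = one_side("above"), below = one_side("below"))
}

#' @export
print.critical_zone_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Critical zone (%s): not measurable (branch band at image edge)\n",
                x$side))
  } else {
    cat(sprintf("Critical zone (%s, > %g degC): %.1f um (mean of %d transects, SD %.1f um)\n",
                x$side, x$threshold_c, x$extent_um, x$n_transects,
                stats::sd(x$per_transect_um)))
  }
  invisible(x)
}
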