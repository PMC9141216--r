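#' Construct a calibrated thermal frame stack
#'
#' A `frame_stack` is the in-memory representation of one thermographic
#' recording of a sealing event: a time-ordered list of 2D temperature grids
#' (degrees Celsius) together with the spatial calibration and the location of
#' the instrument branch band within the image.
#'
#' Image orientation is fixed by convention: row 1 is the top of the image,
#' "above the branches" means rows smaller than `branch_band[1]`, "below"
#' means rows larger than `branch_band[2]`. Rows are 1-based.
#'
#' @param frames List of numeric matrices (degrees Celsius), all of identical
#'   dimensions, or a 3D array with time as the third dimension.
#' @param timestamps Numeric vector of acquisition times in seconds from the
#'   start of the recording, strictly increasing, one per frame.
#' @param calibration Isotropic spatial calibration in micrometers per pixel.
#'   Always an explicit input: the optics of a given recording determine it and
#'   it is never inferred from image content.
#' @param branch_band Integer vector `c(r_top, r_bottom)`: the pixel rows
#'   occupied by the closed instrument branches, `1 <= r_top <= r_bottom <=
#'   nrow`.
#' @param column_roi Integer vector `c(first, last)`: the columns over which
#'   lateral transects are taken. Defaults to the full image width.
#'
#' @return An object of class `frame_stack`.
#'
#' @details Temperatures must be finite and within the plausible instrument
#'   range of -50 to +400 degrees Celsius; values outside are rejected on
#'   construction (and therefore also on load).
#'
#' @examples
#' fr <- matrix(25, 8, 6)
#' fr[4:5, ] <- 90
#' st <- frame_stack(list(fr, fr), timestamps = c(0, 0.5),
#'                   calibration = 100, branch_band = c(4, 5))
#' st
#' @export
frame_stack <- function(frames, timestamps, calibration, branch_band,
                        column_roi = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  }
  if (!is.list(frames) || length(frames) == 0L) {
    stop("'frames' must be a non-empty list of numeric matrices", call. = FALSE)
  }
  if (!all(vapply(frames, is.matrix, logical(1))) ||
      !all(vapply(frames, is.numeric, logical(1)))) {
    stop("every frame must be a numeric matrix", call. = FALSE)
  }
  d1 <- dim(frames[[1]])
  for (k in seq_along(frames)) {
    dk <- dim(frames[[k]])
    if (!identical(dk, d1)) {
      stop(sprintf("frame %d has dimensions %dx%d, expected %dx%d",
                   k, dk[1], dk[2], d1[1], d1[2]), call. = FALSE)
    }
  }
  for (k in seq_along(frames)) {
    v <- frames[[k]]
    if (any(!is.finite(v))) {
      stop(sprintf("frame %d contains non-finite temperatures", k),
           call. = FALSE)
    }
    if (any(v < -50 | v > 400)) {
      stop(sprintf("frame %d contains temperatures outside the plausible range [-50, 400] degC", k),
           call. = FALSE)
    }
  }
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != length(frames)) {
    stop("'timestamps' must have one entry per frame", call. = FALSE)
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("'timestamps' must be strictly increasing", call. = FALSE)
  }
  calibration <- as.numeric(calibration)
  if (length(calibration) != 1L || !is.finite(calibration) || calibration <= 0) {
    stop("'calibration' must be a single positive number (um per pixel)",
         call. = FALSE)
  }
  branch_band <- as.integer(branch_band)
  if (length(branch_band) != 2L || branch_band[1] > branch_band[2] ||
      branch_band[1] < 1L || branch_band[2] > d1[1]) {
    stop("'branch_band' must be rows c(r_top, r_bottom) within the image",
         call. = FALSE)
  }
  if (is.null(column_roi)) column_roi <- c(1L, d1[2])
  column_roi <- as.integer(column_roi)
  if (length(column_roi) != 2L || column_roi[1] > column_roi[2] ||
      column_roi[1] < 1L || column_roi[2] > d1[2]) {
    stop("'column_roi' must be columns c(first, last) within the image",
         call. = FALSE)
  }
  structure(
    list(frames = frames, timestamps = timestamps, calibration = calibration,
         branch_band = branch_band, column_roi = column_roi),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Thermal frame stack: %d frame(s) of %d x %d px\n",
              length(x$frames), d[1], d[2]))
  cat(sprintf("  calibration : %g um/px\n", x$calibration))
  cat(sprintf("  branch band : rows %d-%d (above: %d px, below: %d px)\n",
              x$branch_band[1], x$branch_band[2],
              x$branch_band[1] - 1L, d[1] - x$branch_band[2]))
  cat(sprintf("  column ROI  : %d-%d\n", x$column_roi[1], x$column_roi[2]))
  cat(sprintf("  time span   : %.3g-%.3g s\n",
              x$timestamps[1], x$timestamps[length(x$timestamps)]))
  rng <- range(vapply(x$frames, range, numeric(2)))
  cat(sprintf("  temperature : %.2f-%.2f degC\n", rng[1], rng[2]))
  invisible(x)
}
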