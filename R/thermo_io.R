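#' Write a thermal frame stack to a directory of CSV frames
#'
#' On-disk layout: one CSV matrix per frame, named `frame_0001.csv`,
#' `frame_0002.csv`, ... (zero-padded acquisition order, no header), plus a
#' JSON sidecar `stack.json` holding `calibration` (um/px), `branch_band`,
#' `column_roi` (both 1-based row/column intervals) and `timestamps`
#' (seconds). Temperatures are written with 6 decimal places, so a write/read
#' round trip is lossless to 1e-6 degC. Plain CSV keeps recordings
#' language-agnostic and diff-able; see [write_frame_stack_tiff()] for a
#' compact binary alternative for bulk data.
#'
#' @param stack A [frame_stack()].
#' @param path Directory to create/write into.
#' @return Invisibly, `path`.
#' @seealso [read_frame_stack()]
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", path), call. = FALSE)
  }
  sidecar <- list(
    calibration = stack$calibration,
    branch_band = stack$branch_band,
    column_roi = stack$column_roi,
    timestamps = stack$timestamps
  )
  jsonlite::write_json(sidecar, file.path(path, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_along(stack$frames)) {
    m <- stack$frames[[k]]
    txt <- matrix(sprintf("%.6f", m), nrow = nrow(m))
    utils::write.table(txt, file.path(path, sprintf("frame_%04d.csv", k)),
                       sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a thermal frame stack from a directory of CSV frames
#'
#' Reads the layout produced by [write_frame_stack()]: per-frame CSV matrices
#' ordered by their zero-padded index and a `stack.json` sidecar. All sidecar
#' fields map one-to-one onto the [frame_stack()] fields and the result is
#' fully validated (consistent frame shapes, finite temperatures in the
#' plausible range, geometry inside the image).
#'
#' @param path Directory containing `frame_*.csv` files and `stack.json`.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path) {
  if (!dir.exists(path)) {
    stop(sprintf("directory '%s' does not exist", path), call. = FALSE)
  }
  sidecar_path <- file.path(path, "stack.json")
  if (!file.exists(sidecar_path)) {
    stop(sprintf("format error: sidecar 'stack.json' not found in '%s'", path),
         call. = FALSE)
  }
  sidecar <- jsonlite::fromJSON(sidecar_path)
  needed <- c("calibration", "branch_band", "column_roi", "timestamps")
  missing <- setdiff(needed, names(sidecar))
  if (length(missing)) {
    stop(sprintf("format error: sidecar is missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  files <- sort(list.files(path, pattern = "^frame_[0-9]+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop(sprintf("format error: no frame_*.csv files in '%s'", path),
         call. = FALSE)
  }
  frames <- vector("list", length(files))
  d1 <- NULL
  for (k in seq_along(files)) {
    raw <- utils::read.csv(files[k], header = FALSE,
                           colClasses = "character")
    cells <- as.matrix(raw)
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num))
    if (length(bad)) {
      i <- ((bad[1] - 1L) %% nrow(cells)) + 1L
      j <- ((bad[1] - 1L) %/% nrow(cells)) + 1L
      stop(sprintf("parse error: non-numeric value '%s' in frame %d at row %d, column %d",
                   cells[bad[1]], k, i, j), call. = FALSE)
    }
    m <- matrix(num, nrow = nrow(cells))
    if (is.null(d1)) {
      d1 <- dim(m)
    } else if (!identical(dim(m), d1)) {
      stop(sprintf("format error: frame %d has dimensions %dx%d, expected %dx%d",
                   k, nrow(m), ncol(m), d1[1], d1[2]), call. = FALSE)
    }
    frames[[k]] <- m
  }
  frame_stack(frames,
              timestamps = as.numeric(sidecar$timestamps),
              calibration = as.numeric(sidecar$calibration),
              branch_band = as.integer(sidecar$branch_band),
              column_roi = as.integer(sidecar$column_roi))
}

#' Write a frame stack as a multi-page 32-bit float TIFF
#'
#' Bulk-data alternative to the CSV directory layout. Temperatures are mapped
#' affinely onto `[0, 1]` before storage (32-bit float TIFF pages) and the
#' mapping (`temp_offset`, `temp_scale`, such that `T = value * temp_scale +
#' temp_offset`) is recorded alongside calibration and geometry in a JSON
#' sidecar `<path>.json`. Round-trip error is bounded by float32 resolution of
#' the mapped range (well below 0.001 degC for the instrument range).
#'
#' Requires the optional 'tiff' package.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF file path; the sidecar is written to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_frame_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required for TIFF support", call. = FALSE)
  }
  offset <- -50
  scale <- 450  # instrument range [-50, 400] mapped onto [0, 1]
  pages <- lapply(stack$frames, function(m) (m - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(
    calibration = stack$calibration,
    branch_band = stack$branch_band,
    column_roi = stack$column_roi,
    timestamps = stack$timestamps,
    temp_offset = offset,
    temp_scale = scale
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page float TIFF frame stack
#'
#' Counterpart of [write_frame_stack_tiff()]; reads the TIFF pages and the
#' `<path>.json` sidecar and reverses the affine temperature mapping.
#'
#' @param path TIFF file written by [write_frame_stack_tiff()].
#' @return A [frame_stack()].
#' @export
read_frame_stack_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required for TIFF support", call. = FALSE)
  }
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop(sprintf("format error: sidecar '%s' not found", sidecar_path),
         call. = FALSE)
  }
  sidecar <- jsonlite::fromJSON(sidecar_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(p) {
    p * as.numeric(sidecar$temp_scale) + as.numeric(sidecar$temp_offset)
  })
  frame_stack(frames,
              timestamps = as.numeric(sidecar$timestamps),
              calibration = as.numeric(sidecar$calibration),
              branch_band = as.integer(sidecar$branch_band),
              column_roi = as.integer(sidecar$column_roi))
}
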