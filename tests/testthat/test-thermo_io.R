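test_that("frame-stack write/read round-trips losslessly to 1e-6 degC", {
  set.seed(11)
  for (i in 1:5) {
    st <- random_stack(n_frames = sample(1:4, 1))
    dir <- withr::local_tempdir()
    write_frame_stack(st, dir)
    back <- read_frame_stack(dir)
    expect_equal(length(back$frames), length(st$frames))
    for (k in seq_along(st$frames)) {
      expect_lt(max(abs(back$frames[[k]] - st$frames[[k]])), 1e-6)
    }
    expect_equal(back$calibration, st$calibration)
    expect_identical(back$branch_band, st$branch_band)
    expect_identical(back$column_roi, st$column_roi)
    expect_equal(back$timestamps, st$timestamps)
  }
})

test_that("frame-stack reader rejects malformed directories with located errors", {
  set.seed(12)
  st <- random_stack()
  dir <- withr::local_tempdir()
  write_frame_stack(st, dir)

  # frame 2 with a different shape is named in the error
  bad <- st$frames[[2]][, -1]
  txt <- matrix(sprintf("%.6f", bad), nrow = nrow(bad))
  write.table(txt, file.path(dir, "frame_0002.csv"), sep = ",",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_error(read_frame_stack(dir), "frame 2")

  # a non-numeric cell is located by frame, row and column
  write_frame_stack(st, dir)
  lines <- readLines(file.path(dir, "frame_0003.csv"))
  parts <- strsplit(lines[2], ",")[[1]]
  parts[3] <- "oops"
  lines[2] <- paste(parts, collapse = ",")
  writeLines(lines, file.path(dir, "frame_0003.csv"))
  expect_error(read_frame_stack(dir), "frame 3 at row 2, column 3")

  # missing sidecar is a format error
  file.remove(file.path(dir, "stack.json"))
  expect_error(read_frame_stack(dir), "stack.json")
})

test_that("frame-stack construction enforces its invariants", {
  expect_error(frame_stack(list(), 1, 100, c(1, 1)), "non-empty")
  f <- matrix(25, 4, 4)
  expect_error(frame_stack(list(f, matrix(25, 4, 5)), c(0, 1), 100, c(2, 3)),
               "frame 2 has dimensions")
  expect_error(frame_stack(list(f), 0, -5, c(2, 3)), "calibration")
  expect_error(frame_stack(list(f), 0, 100, c(3, 2)), "branch_band")
  expect_error(frame_stack(list(f, f), c(1, 1), 100, c(2, 3)),
               "strictly increasing")
  expect_error(frame_stack(list(matrix(500, 4, 4)), 0, 100, c(2, 3)),
               "plausible range")
  expect_error(frame_stack(list(matrix(NaN, 4, 4)), 0, 100, c(2, 3)),
               "non-finite")
})

test_that("TIFF round-trip preserves temperatures and metadata", {
  set.seed(13)
  st <- random_stack()
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame_stack_tiff(st, path)
  back <- read_frame_stack_tiff(path)
  for (k in seq_along(st$frames)) {
    expect_lt(max(abs(back$frames[[k]] - st$frames[[k]])), 1e-3)
  }
  expect_equal(back$calibration, st$calibration)
  expect_identical(back$branch_band, st$branch_band)
})

test_that("measurement tables validate, round-trip, and load the packaged dataset", {
  tab <- table1_fixture()
  expect_s3_class(tab, "measurement_table")
  expect_identical(nrow(tab), 60L)
  expect_identical(unname(table(tab$instrument_id, tab$side))[1:4],
                   rep(15L, 4))

  # spot-checks of transcribed rows
  r1 <- tab[tab$instrument_id == "marSeal" & tab$sample_id == 1 &
            tab$side == "above", ]
  expect_equal(r1$critical_extent_um, 2070)
  expect_equal(r1$necrosis_extent_um, 421.9)
  expect_equal(r1$frontier_temp_C, 57.5)
  r2 <- tab[tab$instrument_id == "BiCision" & tab$sample_id == 13 &
            tab$side == "below", ]
  expect_equal(r2$critical_extent_um, 870)
  expect_equal(r2$necrosis_extent_um, 748.8)
  expect_equal(r2$frontier_temp_C, 51.3)

  # write/read round-trip including the extra printed-index column
  path <- withr::local_tempfile(fileext = ".tsv")
  write_measurements(tab, path)
  back <- read_measurements(path)
  expect_equal(back$critical_extent_um, tab$critical_extent_um)
  expect_equal(back$rilate_printed, tab$rilate_printed)

  # invariant violations are located
  bad <- tab
  bad$necrosis_extent_um[1] <- bad$critical_extent_um[1] + 1
  expect_error(measurement_table(bad), "exceeds critical extent")
  dup <- rbind(tab, tab[1, ])
  expect_error(measurement_table(dup), "duplicate measurement key")

  # header-only file loads as an empty, valid table
  writeLines(paste(c("instrument_id", "sample_id", "side",
                     "critical_extent_um", "necrosis_extent_um",
                     "frontier_temp_C"), collapse = "\t"), path)
  expect_identical(nrow(read_measurements(path)), 0L)
})
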