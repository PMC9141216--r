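test_that("max projection equals the brute-force elementwise maximum", {
  set.seed(21)
  st <- random_stack(n_frames = 5L)
  proj <- max_projection(st)
  brute <- st$frames[[1]]
  for (k in 2:5) brute <- pmax(brute, st$frames[[k]])
  expect_identical(proj, brute)

  # single frame: identity; appending a uniformly hotter frame wins
  one <- frame_stack(st$frames[1], st$timestamps[1], st$calibration,
                     st$branch_band, st$column_roi)
  expect_identical(max_projection(one), st$frames[[1]])
  hot <- lapply(st$frames, function(f) f * 0 + 150)
  st2 <- frame_stack(c(st$frames, hot[1]),
                     c(st$timestamps, max(st$timestamps) + 1),
                     st$calibration, st$branch_band, st$column_roi)
  expect_true(all(max_projection(st2) == 150))
})

test_that("appending colder frames changes neither projection nor extents", {
  m <- noiseless_model()
  ev <- simulate_event(m, seed = 30)
  st <- ev$stack
  before <- measure_sample(st)
  colder <- lapply(st$frames[1:2], function(f) f - 5)
  st2 <- frame_stack(c(st$frames, colder),
                     c(st$timestamps, max(st$timestamps) + c(1, 2)),
                     st$calibration, st$branch_band, st$column_roi)
  after <- measure_sample(st2)
  expect_equal(after$above$extent_um, before$above$extent_um)
  expect_equal(after$below$extent_um, before$below$extent_um)
})

test_that("transect columns are evenly spaced and the single transect is central", {
  proj <- matrix(60, 10, 12)
  ps <- extract_transects(proj, 100, c(5L, 6L), c(2L, 11L), n_transects = 1L)
  expect_identical(unique(vapply(ps, `[[`, integer(1), "column")), 6L)
  ps2 <- extract_transects(proj, 100, c(5L, 6L), c(2L, 11L), n_transects = 5L)
  cols <- unique(vapply(ps2, `[[`, integer(1), "column"))
  expect_identical(cols, as.integer(round(seq(2, 11, length.out = 5))))
  expect_error(extract_transects(proj, 100, c(5L, 6L), c(2L, 11L), 11L),
               "ROI width")

  # distances start at zero with one-pixel spacing and profiles leave the band
  p <- ps2[[1]]
  expect_identical(p$distances[1], 0)
  expect_equal(unique(diff(p$distances)), 100)
  expect_length(p$temperatures, 4L)  # rows 4..1 above the band
})

test_that("noiseless profiles decay monotonically away from the band", {
  ev <- simulate_event(noiseless_model(), seed = 31)
  proj <- max_projection(ev$stack)
  st <- ev$stack
  ps <- extract_transects(proj, st$calibration, st$branch_band,
                          st$column_roi, 15L)
  for (p in ps) expect_true(all(diff(p$temperatures) <= 0))
})

test_that("a branch band at the image edge flags that side as absent", {
  m <- event_model(branch_band = c(1L, 4L), noise_sd = 0)
  ev <- simulate_event(m, seed = 32)
  res <- measure_sample(ev$stack)
  expect_true(res$above$degenerate)
  expect_true(is.na(res$above$extent_um))
  expect_false(res$below$degenerate)
})

test_that("supra-threshold extent interpolates the boundary sub-pixel", {
  # two full 100-um steps above 50 degC, then a crossing midway 60 -> 40
  p <- make_profile(c(80, 70, 60, 40))
  expect_equal(critical_extent(p), 250)
  # strictly-greater rule: a pixel at exactly 50.0 terminates the zone
  expect_equal(critical_extent(make_profile(c(80, 50, 40))), 100 * 30 / 30)
  expect_equal(critical_extent(make_profile(c(50, 49))), 0)
  expect_equal(critical_extent(make_profile(c(30, 20))), 0)
  # never crossing: truncated at the field edge, with a warning
  expect_warning(out <- critical_extent(make_profile(c(90, 80, 70))),
                 "truncated")
  expect_equal(out, 200)
})

test_that("raising the threshold never increases the extent", {
  set.seed(33)
  for (i in 1:20) {
    temps <- rev(sort(runif(12, 20, 120)))
    p <- make_profile(temps, spacing = 50)
    ext <- vapply(c(45, 50, 60, 75, 90), function(th) {
      suppressWarnings(critical_extent(p, th))
    }, numeric(1))
    expect_true(all(diff(ext) <= 1e-9))
  }
})

test_that("measured extents match the closed form on noiseless events", {
  set.seed(34)
  for (i in 1:10) {
    m <- noiseless_model(
      t_ambient = runif(1, 18, 25),
      t_peak = runif(1, 80, 120),
      lambda_above = runif(1, 800, 2500),
      lambda_below = runif(1, 600, 2000)
    )
    ev <- simulate_event(m)
    res <- measure_sample(ev$stack)
    half_px <- m$calibration / 2
    expect_lt(abs(res$above$extent_um - ev$truth$critical_above_um), half_px)
    expect_lt(abs(res$below$extent_um - ev$truth$critical_below_um), half_px)
    # translation-invariant noiseless field: all transects agree exactly
    expect_equal(var(res$above$per_transect_um), 0)
  }
})

test_that("noisy extents carry the predicted small positive max-projection bias", {
  # Reading a threshold crossing off a per-pixel maximum over k noisy frames
  # shifts the profile up by at most E[max of k N(0, sd)] and therefore the
  # crossing outward by at most that shift divided by the local profile
  # slope. The measured bias must be positive (upward) but below this
  # first-order bound; it is not zero, which is a documented property of the
  # peak-exposure definition, not an implementation defect.
  set.seed(35)
  m <- event_model(noise_sd = 2, ramp_time = 1, plateau_time = 1,
                   frame_interval = 0.5)
  truth <- critical_extent_analytic(m$lambda_above, m$t_ambient, m$t_peak)
  ests <- vapply(1:50, function(i) {
    measure_sample(simulate_event(m)$stack)$above$extent_um
  }, numeric(1))
  bias <- mean(ests) - truth
  se <- sd(ests) / sqrt(length(ests))

  k <- length(seq(0, m$ramp_time + m$plateau_time, by = m$frame_interval))
  e_max <- k * integrate(function(z) z * dnorm(z) * pnorm(z)^(k - 1),
                         -Inf, Inf)$value * m$noise_sd
  slope <- (50 - m$t_ambient) / m$lambda_above   # |dT/dd| at the crossing
  expect_gt(bias, 2 * se)            # genuinely biased upward ...
  expect_lt(bias, e_max / slope)     # ... but within the first-order bound
  expect_lt(bias, 2 * m$calibration) # and small on the scale of the zone
})

test_that("temperature lookup interpolates and inverts the frontier", {
  p <- make_profile(c(80, 70, 60, 40))
  expect_equal(temperature_at(p, 0), 80)      # first off-band pixel
  expect_equal(temperature_at(p, 200), 60)    # exact pixel centre
  expect_equal(temperature_at(p, 150), 65)    # midway interpolation
  expect_error(temperature_at(p, 400), "within")
  expect_error(temperature_at(p, -1), "within")

  # inversion consistency: reading the temperature at the generated necrosis
  # margin recovers the sampled frontier temperature
  ev <- simulate_event(noiseless_model(), seed = 36)
  st <- ev$stack
  ps <- extract_transects(max_projection(st), st$calibration,
                          st$branch_band, st$column_roi, 1L)
  above <- Filter(function(p) p$side == "above", ps)[[1]]
  got <- temperature_at(above, ev$truth$necrosis_above_um)
  expect_lt(abs(got - ev$truth$frontier_above_c), 0.5)

  # and the necrosis extent is itself a crossing of the same profile
  ninv <- critical_extent(above, threshold_c = ev$truth$frontier_above_c)
  expect_lt(abs(ninv - ev$truth$necrosis_above_um), st$calibration / 2)
})
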