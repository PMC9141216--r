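# Shared generators for tests. All randomness is seeded by the caller.

random_stack <- function(n_frames = 3L, n_rows = 6L, n_cols = 5L) {
  frames <- replicate(n_frames,
                      matrix(runif(n_rows * n_cols, 15, 120), n_rows, n_cols),
                      simplify = FALSE)
  frame_stack(frames,
              timestamps = cumsum(runif(n_frames, 0.1, 0.5)),
              calibration = runif(1, 20, 400),
              branch_band = c(3L, 4L),
              column_roi = c(2L, n_cols - 1L))
}

# direct profile constructor for unit-testing the boundary arithmetic
make_profile <- function(temps, spacing = 100, side = "above") {
  rilate:::.transect_profile(side, 1L, (seq_along(temps) - 1) * spacing,
                             temps)
}

# a small, fast noiseless model for oracle tests
noiseless_model <- function(...) {
  event_model(noise_sd = 0, ramp_time = 1, plateau_time = 1,
              frame_interval = 0.5, ...)
}

# brute-force two-sided Mann-Whitney p by enumerating all C(N, n1) group
# assignments of the pooled mid-ranks (independent oracle for the exact paths)
brute_force_mwu_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  mu <- n1 * mean(r)
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  combos <- utils::combn(length(pooled), n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(sums - mu) >= obs - 1e-9)
}
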