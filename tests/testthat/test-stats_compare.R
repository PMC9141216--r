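test_that("the exact path matches hand-enumerated small cases", {
  # {1,2} vs {3,4}: U = 0; 1 of the 6 equally likely rank assignments is as
  # extreme on each side, so the two-sided p is 2/6
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_identical(res$method, "exact")
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$U1 + res$U2, res$n1 * res$n2)
})

test_that("U invariants and label symmetry hold across random cases", {
  set.seed(51)
  for (i in 1:20) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    # mix tie-free and tied data
    x <- if (i %% 2) rnorm(n1) else sample(1:4, n1, replace = TRUE)
    y <- if (i %% 2) rnorm(n2) else sample(1:4, n2, replace = TRUE)
    a <- mann_whitney_u(x, y)
    b <- mann_whitney_u(y, x)
    expect_gte(a$U, 0)
    expect_lte(a$U, n1 * n2)
    expect_equal(a$U1 + a$U2, n1 * n2)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_gt(a$p_value, 0)
    expect_lte(a$p_value, 1)
  }
})

test_that("exact p agrees with stats::wilcox.test on tie-free data", {
  set.seed(52)
  for (i in 1:10) {
    x <- rnorm(sample(3:12, 1))
    y <- rnorm(sample(3:12, 1))
    res <- mann_whitney_u(x, y)
    expect_identical(res$method, "exact")
    expect_equal(res$p_value, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("the mid-rank path equals brute-force permutation enumeration", {
  set.seed(53)
  for (i in 1:10) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    x <- sample(1:5, n1, replace = TRUE)
    y <- sample(1:5, n2, replace = TRUE)
    res <- mann_whitney_u(x, y)
    if (!res$ties) next
    expect_identical(res$method, "exact_midrank")
    expect_equal(res$p_value, brute_force_mwu_p(x, y), tolerance = 1e-12)
  }
})

test_that("degenerate and invalid inputs are handled", {
  res <- mann_whitney_u(rep(3, 5), rep(3, 7))
  expect_equal(res$p_value, 1)
  expect_true(res$ties)
  expect_equal(mann_whitney_u(c(1, 5, 2), c(1, 5, 2))$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  expect_error(mann_whitney_u(c(1, NA), 1:3), "finite")
  expect_error(mann_whitney_u(c(1, 1, 2), 2:4, method = "exact"), "tie-free")
})

test_that("the normal approximation tracks wilcox.test and the exact tail", {
  set.seed(54)
  x <- rnorm(30); y <- rnorm(35, 0.5)
  res <- mann_whitney_u(x, y)
  expect_identical(res$method, "normal_approx")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(res$p_value, ref, tolerance = 1e-9)

  # with ties and large n the tie-corrected variance is used
  xt <- sample(1:6, 30, replace = TRUE)
  yt <- sample(1:6, 30, replace = TRUE) + 1
  rest <- mann_whitney_u(xt, yt)
  expect_identical(rest$method, "normal_approx")
  reft <- wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value
  expect_equal(rest$p_value, reft, tolerance = 1e-9)
})

test_that("p falls with increasing location shift, in expectation", {
  set.seed(55)
  mean_p <- vapply(c(0, 0.8, 1.6), function(shift) {
    mean(vapply(1:30, function(i) {
      mann_whitney_u(rnorm(12), rnorm(12, shift))$p_value
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_p) < 0))
})

test_that("the eight study comparisons run in fixed order with printed tags", {
  cmp <- run_study_comparisons(table1_fixture())
  expect_identical(nrow(cmp), 8L)
  expect_identical(cmp$instrument_id, rep(c("marSeal", "BiCision"), each = 4))
  expect_identical(cmp$quantity[1:4],
                   c("critical_extent", "necrosis_extent",
                     "frontier_temperature", "sample_rilate"))
  # the index comparison uses full-precision per-row ratios: tie-free, exact
  expect_identical(cmp$method[cmp$quantity == "sample_rilate"],
                   c("exact", "exact"))
  # borderline flag marks the one comparison printed at exactly p = 0.05
  expect_identical(which(cmp$borderline), 4L)
  expect_error(run_study_comparisons(
    measurement_table(table1_fixture()[1:15, ])), "both sides")
})
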