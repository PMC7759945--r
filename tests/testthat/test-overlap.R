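test_that("identical samples give complete overlap", {
  set.seed(31)
  tt <- rvm(120, 2, 3)
  expect_identical(overlap_delta4(tt, tt), 1)
  expect_gt(overlap_delta1(tt, tt), 0.98)
})

test_that("antipodal schedules give near-zero overlap", {
  set.seed(32)
  a <- rvm(200, hours_to_radians(6), 8)
  b <- rvm(200, hours_to_radians(18), 8)
  expect_lt(overlap_delta1(a, b), 0.10)
  expect_lt(overlap_delta4(a, b), 0.10)
})

test_that("overlap estimates stay in [0,1] and are symmetric", {
  set.seed(33)
  for (rep in 1:8) {
    a <- rvm(80, runif(1, 0, 2 * pi), runif(1, 0.5, 6))
    b <- rvm(80, runif(1, 0, 2 * pi), runif(1, 0.5, 6))
    d1 <- overlap_delta1(a, b)
    d4 <- overlap_delta4(a, b)
    expect_gte(d1, 0); expect_lte(d1, 1)
    expect_gte(d4, 0); expect_lte(d4, 1)
    expect_equal(overlap_delta1(b, a), d1, tolerance = 1e-12)
    expect_equal(overlap_delta4(b, a), d4, tolerance = 1e-12)
  }
})

test_that("samples from one distribution overlap almost completely", {
  set.seed(34)
  d1 <- replicate(100, overlap_delta1(rvm(50, hours_to_radians(12), 2),
                                      rvm(50, hours_to_radians(12), 2)))
  expect_gt(mean(d1), 0.85)
  expect_lt(mean(d1), 0.98)
})

test_that("the two estimators agree on moderately overlapping samples", {
  set.seed(35)
  diffs <- replicate(8, {
    a <- rvm(200, hours_to_radians(10), 2)
    b <- rvm(200, hours_to_radians(14), 2)
    overlap_delta1(a, b) - overlap_delta4(a, b)
  })
  expect_true(all(abs(diffs) < 0.05))
})

test_that("estimator selection follows the small-sample rule", {
  expect_equal(select_estimator(61, 945), "delta1")
  expect_equal(select_estimator(75, 75), "delta4")
  expect_equal(select_estimator(2, 2), "delta1")
  expect_equal(overlap_estimate(rvm(10, 0, 2), rvm(100, 0, 2))$estimator,
               "delta1")
})

test_that("overlap strength categories split at 0.5 and 0.75", {
  expect_equal(classify_strength(0.87), "strong")
  expect_equal(classify_strength(0.35), "low")
  expect_equal(classify_strength(0.6), "moderate")
  expect_equal(classify_strength(0.5), "low")
  expect_equal(classify_strength(0.75), "moderate")
  expect_error(classify_strength(1.2))
})

test_that("bootstrap CI brackets high and low overlap appropriately", {
  set.seed(36)
  tt <- rvm(100, 2, 3)
  ci_same <- overlap_ci(tt, tt, n_boot = 200, seed = 9)
  expect_gte(ci_same$ci_high, 0.95)
  a <- rvm(100, hours_to_radians(6), 8)
  b <- rvm(100, hours_to_radians(18), 8)
  ci_far <- overlap_ci(a, b, n_boot = 200, seed = 9)
  expect_lt(ci_far$ci_high, 0.3)
  # CI narrows with sample size under the same generator
  w <- sapply(c(50, 500), function(n) {
    set.seed(100 + n)
    ci <- overlap_ci(rvm(n, hours_to_radians(10), 2),
                     rvm(n, hours_to_radians(13), 2),
                     n_boot = 200, seed = 11)
    ci$ci_high - ci$ci_low
  })
  expect_lt(w[2], w[1])
})

test_that("same-distribution permutation test separates shared from disjoint", {
  set.seed(37)
  tt <- rvm(100, 2, 3)
  expect_equal(same_distribution_test(tt, tt, n_boot = 99,
                                      seed = 5)$p_value, 1)
  a <- rvm(100, hours_to_radians(6), 4)
  b <- rvm(100, hours_to_radians(18), 4)
  expect_lt(same_distribution_test(a, b, n_boot = 499, seed = 5)$p_value,
            0.01)
})

test_that("Watson U2 is near zero for identical samples and large when disjoint", {
  set.seed(38)
  a <- rvm(100, 2, 3)
  w <- suppressWarnings(watson_two_sample(a, a))
  expect_lt(w$u2, 0.05)
  expect_equal(w$p_band, "p > 0.1")
  d <- watson_two_sample(rvm(100, hours_to_radians(6), 4),
                         rvm(100, hours_to_radians(18), 4))
  expect_lt(d$p_value, 0.01)
  expect_equal(d$p_band, "p < 0.01")
  # matched samples usually land in the acceptance band
  ok <- replicate(10, {
    watson_two_sample(rvm(100, 1, 2), rvm(100, 1, 2))$p_value > 0.1
  })
  expect_gte(mean(ok), 0.8)
  expect_error(watson_two_sample(rvm(5, 0, 1), rvm(100, 0, 1)))
})

test_that("pairwise overlap matrix is symmetric with unit diagonal", {
  set.seed(39)
  ev <- data.frame(
    station = "s1", species = rep(sprintf("sp%d", 1:5), each = 60),
    time_rad = c(rvm(60, 1, 3), rvm(60, 2, 3), rvm(60, 3, 3),
                 rvm(60, 4, 3), rvm(60, 5, 3)))
  om <- overlap_matrix(ev, seed = 3)
  expect_equal(om$matrix, t(om$matrix))
  expect_equal(unname(diag(om$matrix)), rep(1, 5))
  expect_equal(nrow(om$pairs), 10)
  expect_true(all(om$pairs$strength %in% c("low", "moderate", "strong")))
  ex <- overlap_matrix(ev, exclude = "sp5", seed = 3)
  expect_equal(nrow(ex$matrix), 4)
})
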