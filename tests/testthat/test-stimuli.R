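test_that("gaussian stimulus has the right peak and half-width", {
  expect_equal(gaussian_stimulus(50, 10, 3, amplitude = 0), rep(0, 50))
  s <- gaussian_stimulus(240, center = 85, width = 25 / sqrt(2 * log(2)),
                         amplitude = 2)
  expect_equal(s[85], 2)
  expect_equal(which.max(s), 85)
  # half-maximum crossings near channels 60 and 110
  above <- which(s > 1)
  expect_equal(range(above), c(61, 109), tolerance = 1)
  expect_error(gaussian_stimulus(50, 10, 0), "width")
  expect_error(gaussian_stimulus(50, 10, 3, -1), "amplitude")
})

test_that("naturalistic calibration pins the 40th percentile and maximum", {
  out <- preprocess_naturalistic(0:9)
  expect_equal(max(out), 1)
  # sort-based percentile oracle for the 40th percentile of 0..9 (type 7):
  # h = (10 - 1) * 0.4 + 1 = 4.6 -> x(4) + 0.6 (x(5) - x(4)) = 3.6
  expect_equal(out, (0:9 - 3.6) / (9 - 3.6))
  expect_true(any(out < 0)) # sub-percentile values stay negative

  # a value sitting exactly at the 40th percentile maps to zero:
  # for n = 6, h = (6 - 1) * 0.4 + 1 = 3, the third order statistic
  x <- c(10, 2, 8, 4, 6, 12)
  out2 <- preprocess_naturalistic(x)
  expect_equal(out2[x == sort(x)[3]], 0)

  expect_error(preprocess_naturalistic(rep(1, 5)), "distinct")
  expect_error(preprocess_naturalistic(1), "distinct")
})

test_that("mixtures combine, add air and rectify", {
  expect_equal(mix_stimuli(c(1, 0), c(0, 1), p = 0.6, air_level = 0.1),
               c(0.7, 0.5))
  a <- c(1, 0.5, -2)
  expect_equal(mix_stimuli(a, a * 0, p = 1, air_level = 0.1),
               pmax(a + 0.1, 0))
  expect_equal(mix_stimuli(c(-1), c(-1), 0.5, 0.1), 0) # rectified
  expect_error(mix_stimuli(1, c(1, 2), 0.5, 0.1), "length")
  expect_error(mix_stimuli(1, 1, 1.5, 0.1), "\\[0, 1\\]")
})

test_that("presented stimuli are nonnegative and include air", {
  s <- simplified_stimuli(n_mc = 60, centers = c(20, 40), width = 5)
  for (o in c("A", "B", "air")) {
    v <- presented_stimulus(s, o)
    expect_true(all(is.finite(v) & v >= 0))
  }
  expect_equal(presented_stimulus(s, "air"), rep(0.2, 60))
  expect_equal(max(presented_stimulus(s, "A")), 2.2)
})

test_that("surrogate glomerular sets hit their similarity targets", {
  s <- surrogate_glomerular_set(4, n_mc = 240,
                                similarity = c(1, 0.7, 0.3, 0),
                                rng_seed = 11)
  pats <- as.matrix(s)
  expect_equal(unname(cor(pats[, 1], pats[, 2])), 0.7, tolerance = 0.05)
  expect_equal(unname(cor(pats[, 1], pats[, 3])), 0.3, tolerance = 0.05)
  expect_lt(abs(cor(pats[, 1], pats[, 4])), 0.05)
  # one-factor structure for non-reference pairs
  expect_equal(unname(cor(pats[, 2], pats[, 3])), 0.7 * 0.3,
               tolerance = 0.05)
  # calibration: max 1, ~60% of channels above zero
  expect_equal(unname(apply(pats, 2, max)), rep(1, 4))
  expect_equal(unname(colMeans(pats > 0)), rep(0.6, 4), tolerance = 0.02)

  # requested similarity 1 gives identical patterns
  s1 <- surrogate_glomerular_set(2, similarity = c(1, 1), rng_seed = 3)
  expect_equal(s1$patterns[, 1], s1$patterns[, 2], ignore_attr = TRUE)

  # determinism
  a <- surrogate_glomerular_set(3, similarity = 0.4, rng_seed = 5)
  b <- surrogate_glomerular_set(3, similarity = 0.4, rng_seed = 5)
  expect_identical(a$patterns, b$patterns)
  expect_error(surrogate_glomerular_set(2, similarity = c(1, 2)), "\\[-1, 1\\]")
})

test_that("hard-task mixtures are more similar than the base pair", {
  set.seed(17)
  for (i in 1:10) {
    s <- surrogate_glomerular_set(3, similarity = c(1, runif(1, 0, 0.5),
                                                    runif(1, 0, 0.5)))
    a <- presented_stimulus(s, 2)
    b <- presented_stimulus(s, 3)
    m1 <- mix_stimuli(s$patterns[, 2], s$patterns[, 3], 0.6, s$air_level)
    m2 <- mix_stimuli(s$patterns[, 2], s$patterns[, 3], 0.4, s$air_level)
    expect_gt(stimulus_similarity(m1, m2), stimulus_similarity(a, b))
  }
})

test_that("block-average downsampling preserves means", {
  z <- rep(c(1, 3, 5, 7), each = 10)
  expect_equal(downsample_pattern(z, 4), c(1, 3, 5, 7))
  set.seed(1)
  z1 <- rnorm(120)
  expect_equal(mean(downsample_pattern(z1, 40)), mean(z1)) # equal blocks
  expect_equal(downsample_pattern(z1, 120), z1)            # identity
  expect_equal(length(downsample_pattern(seq_len(2074), 240)), 240)
})
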