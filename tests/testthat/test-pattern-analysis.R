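test_that("trial classification follows the extremal-player rules", {
  hb <- c(1.2, 3.5, 5.8)
  r1 <- classify_trial(hb, c(0.4, -0.1, -0.3))
  expect_equal(r1$label, "P1")
  expect_equal(r1$influence_leader, 1L)
  expect_equal(r1$phase_leader, 1L)

  expect_equal(classify_trial(hb, c(-0.3, -0.1, 0.4))$label, "P2")

  r3 <- classify_trial(hb, c(0.30, -0.58, 0.28), p3_tolerance = 0.2)
  expect_equal(r3$label, "P3")
  expect_equal(r3$influence_leader, c(1L, 3L))

  # top flow at the middle player fits no pattern
  expect_equal(classify_trial(hb, c(-0.1, 0.4, -0.3))$label, "NONE")

  expect_error(classify_trial(c(1, 2), c(0, 0)), "3 players")
  expect_error(classify_trial(c(1, 1, 1), c(1, 0, -1)), "all-equal")
})

test_that("classification is invariant to allowed rescalings", {
  set.seed(21)
  for (r in 1:20) {
    hb <- runif(7, 1, 7)
    net <- rnorm(7)
    base <- classify_trial(hb, net)$label
    expect_equal(classify_trial(hb, net + 5)$label, base)
    expect_equal(classify_trial(2.5 * hb + 1, net)$label, base)
  }
})

test_that("prose orientation swaps the roles of the phase extremes", {
  hb <- c(1.2, 3.5, 5.8)
  net <- c(0.4, -0.1, -0.3)
  expect_equal(classify_trial(hb, net, orientation = "prose")$label, "P2")
})

test_that("pattern frequencies pool labels correctly", {
  labs <- c(rep("P1", 3), "P2", "P3", rep("NONE", 3))
  f <- pattern_frequencies(labs)
  expect_equal(f$any_pattern, 0.625)
  expect_equal(sum(f$counts), 8)
  expect_equal(sum(f$fractions), 1)
  expect_equal(pattern_frequencies(rep("NONE", 5))$any_pattern, 0)
  expect_equal(unname(as.vector(pattern_frequencies("P1")$fractions)),
               c(1, 0, 0, 0))
  expect_error(pattern_frequencies(character(0)), "no trials")
})

test_that("chance pattern frequency is two over the group size", {
  expect_equal(round(100 * chance_pattern_frequency(7), 2), 28.57)
  expect_equal(chance_pattern_frequency(4), 0.5)
  expect_equal(chance_pattern_frequency(100), 0.02)
  expect_error(chance_pattern_frequency(2), "at least 3")
})

test_that("outlier removal drops gross residuals and respects the cap", {
  x <- seq_len(12)
  y <- 2 * x + 1
  x_out <- c(x, 6.5); y_out <- c(y, 2 * 6.5 + 1 + 50)
  cl <- remove_outliers(x_out, y_out)
  expect_equal(cl$removed, 1L)
  expect_equal(cl$which, 13L)

  clean <- remove_outliers(x, y)
  expect_equal(clean$removed, 0L)

  small <- remove_outliers(c(1, 2, 3, 4), c(1, 2, 3, 40))
  expect_gte(length(small$x), 3)   # cap floor(n/10) = 0 removals
  expect_error(remove_outliers(1:3, 1:3), "at least 4")
})

test_that("pattern characterization fits the stated polynomial geometry", {
  x <- seq(-3, 3, length.out = 15)
  perfect <- characterize_pattern(x, 2 * x + 1, degree = 1)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$r_squared, 1)

  xs <- c(-2, -1, 0, 1, 2)
  ys <- xs^2
  lin <- characterize_pattern(xs, ys, degree = 1, trim_outliers = FALSE)
  expect_equal(lin$pearson_r, 0)
  expect_equal(lin$r_squared, 0)
  par <- characterize_pattern(xs, ys, degree = 2, trim_outliers = FALSE)
  expect_equal(par$r_squared, 1)
  expect_equal(par$coefficients, c(0, 0, 1), tolerance = 1e-10)

  set.seed(31)
  xr <- runif(100, -2, 2)
  yr <- -0.5 * xr + rnorm(100, sd = 0.1)
  noisy <- characterize_pattern(xr, yr, degree = 1)
  expect_lt(noisy$pearson_r, 0)
  expect_lt(noisy$p_value, 0.001)

  expect_error(characterize_pattern(rep(1, 10), rnorm(10)), "degenerate")
})

test_that("a linear generating slope is recovered with the right sign", {
  set.seed(32)
  signs <- sapply(1:50, function(r) {
    x <- runif(30, 1, 7)
    y <- -0.08 * x + rnorm(30, sd = 0.05)
    sign(characterize_pattern(x, y, degree = 1)$coefficients[2])
  })
  expect_true(all(signs == -1))
})

test_that("pattern-by-topology tabulates and tests against uniformity", {
  labs <- c(rep("P1", 8), rep("NONE", 8))
  tops <- rep(c("complete", "path", "ring", "star"), 4)
  even <- pattern_by_topology(labs, tops)
  expect_equal(even$test$statistic, 0)

  labs2 <- c(rep("P1", 20), rep("P2", 4), rep("P3", 4), rep("P1", 4))
  tops2 <- c(rep("complete", 20), rep("path", 4), rep("ring", 4),
             rep("star", 4))
  skew <- pattern_by_topology(labs2, tops2)
  expect_equal(skew$test$statistic, 24)
  expect_equal(skew$test$df, 3)

  expect_error(pattern_by_topology(labs, rep("ring", 16)), "2 topologies")
})
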