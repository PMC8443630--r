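test_that("order parameter hits its analytic values", {
  common <- matrix(rep(seq(0, 10, length.out = 50), 7), 50, 7)
  expect_equal(order_parameter(common)$z, rep(1, 50))

  anti <- cbind(seq(0, 5, length.out = 40),
                seq(0, 5, length.out = 40) + pi)
  expect_equal(order_parameter(anti)$z, rep(0, 40), tolerance = 1e-12)

  quarter <- matrix(c(0, pi / 2), 1, 2)
  expect_equal(order_parameter(quarter)$z_bar, sqrt(2) / 2)
})

test_that("order parameter is invariant under a common rotation", {
  set.seed(41)
  th <- matrix(rnorm(200), 40, 5)
  shift <- runif(40, -10, 10)
  expect_equal(order_parameter(th)$z, order_parameter(th + shift)$z,
               tolerance = 1e-12)
})

test_that("chi-squared goodness of fit matches hand totals and base R", {
  eq <- chi_square_gof(c(5, 5, 5), c(5, 5, 5))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  sk <- chi_square_gof(c(50, 10, 10, 10), rep(20, 4))
  expect_equal(sk$statistic, 60)
  expect_equal(sk$df, 3)

  expect_equal(chi_square_gof(c(20, 4, 4, 4), rep(8, 4))$statistic, 24)

  set.seed(42)
  o <- as.numeric(table(sample(1:4, 200, replace = TRUE, prob = c(4, 3, 2, 1))))
  ref <- suppressWarnings(stats::chisq.test(o, p = c(0.4, 0.3, 0.2, 0.1)))
  mine <- chi_square_gof(o, c(0.4, 0.3, 0.2, 0.1))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
  expect_error(chi_square_gof(c(1, 2), c(1, 0)), "positive")
})

test_that("pooled t-test matches base R and behaves symmetrically", {
  set.seed(43)
  a <- rnorm(40, 1); b <- rnorm(35)
  mine <- independent_t_test(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)

  swap <- independent_t_test(b, a)
  expect_equal(swap$statistic, -mine$statistic)
  expect_equal(swap$p_value, mine$p_value)

  same <- independent_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  big_a <- rnorm(1000, 1); big_b <- rnorm(1000, 0)
  big <- independent_t_test(big_a, big_b)
  expect_gt(big$statistic, 10)
  expect_lt(big$p_value, 1e-10)
  expect_error(independent_t_test(rep(1, 5), rep(1, 5)), "pooled variance")
})

test_that("Cohen's d uses the pooled standard deviation", {
  expect_equal(cohens_d_summary(0.73, 0.17, 40, 0.60, 0.17, 40),
               0.13 / 0.17, tolerance = 1e-12)
  set.seed(44)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(cohens_d(a, a), 0)
  expect_equal(cohens_d(3 * a, 3 * b), cohens_d(a, b), tolerance = 1e-12)
})

test_that("one-way ANOVA matches base R with eta-squared", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  flat <- one_way_anova(g)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$effect_size, 0)

  set.seed(45)
  a <- rnorm(20); b <- rnorm(20, 0.8)
  two <- one_way_anova(list(a, b))
  tt <- independent_t_test(a, b)
  expect_equal(two$statistic, tt$statistic^2, tolerance = 1e-10)

  groups <- lapply(c(0, 0, 0, 3), function(m) rnorm(20, m))
  res <- one_way_anova(groups)
  ref <- summary(stats::aov(y ~ g, data.frame(
    y = unlist(groups), g = factor(rep(1:4, each = 20)))))[[1]]
  expect_equal(res$statistic, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-8)
  expect_gt(res$effect_size, 0.4)
  expect_error(one_way_anova(list(rep(1, 3), rep(2, 3))), "variance")
})

test_that("D'Agostino-Pearson omnibus matches the reference implementation", {
  # frozen values from an independent implementation of the omnibus test
  set.seed(42); x <- rnorm(50)
  set.seed(43); y <- rexp(60)
  rx <- dagostino_pearson(x)
  ry <- dagostino_pearson(y)
  expect_equal(rx$statistic, 0.6863994613, tolerance = 1e-8)
  expect_equal(rx$p_value, 0.7094964892, tolerance = 1e-8)
  expect_equal(ry$statistic, 12.9199014545, tolerance = 1e-8)
  expect_equal(ry$p_value, 0.0015648728, tolerance = 1e-8)
  expect_error(dagostino_pearson(rnorm(5)), "at least 8")
})
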