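test_that("gaussian entropy matches closed forms for normal samples", {
  set.seed(1)
  x <- rnorm(50000)
  expect_equal(shannon_entropy(x), 0.5 * log(2 * pi * exp(1)),
               tolerance = 0.01)
  # affine shift: scaling by c adds log|c|
  expect_equal(shannon_entropy(3 * x) - shannon_entropy(x), log(3),
               tolerance = 1e-10)
  xy <- matrix(rnorm(2 * 50000), ncol = 2)
  expect_equal(shannon_entropy(xy), log(2 * pi * exp(1)), tolerance = 0.02)
  expect_error(shannon_entropy(cbind(x, x)), "singular")
})

test_that("k-NN entropy agrees with closed forms at moderate n", {
  set.seed(2)
  es <- estimator_spec("knn")
  expect_equal(shannon_entropy(rnorm(4000), es), 0.5 * log(2 * pi * exp(1)),
               tolerance = 0.05)
  expect_equal(shannon_entropy(matrix(rnorm(8000), ncol = 2), es),
               log(2 * pi * exp(1)), tolerance = 0.05)
  expect_error(shannon_entropy(rep(c(1, 2), 50), es), "duplicate")
})

test_that("transfer entropy matches the closed form on the driven pair", {
  p <- ar_pair(a = 1, n = 50000, seed = 3)
  expect_equal(transfer_entropy(p$x, p$y), 0.5 * log(2), tolerance = 0.02)

  # error shrinks with sample size (O(1/sqrt(n)) consistency)
  p_small <- ar_pair(a = 1, n = 5000, seed = 4)
  p_big <- ar_pair(a = 1, n = 50000, seed = 4)
  expect_lt(abs(transfer_entropy(p_small$x, p_small$y) - 0.5 * log(2)), 0.05)
  expect_lt(abs(transfer_entropy(p_big$x, p_big$y) - 0.5 * log(2)), 0.02)

  # independent series carry no flow
  q <- ar_pair(a = 0, n = 20000, seed = 5)
  expect_lte(transfer_entropy(q$x, q$y), 0.005)

  # nonnegative for arbitrary inputs (clipped estimator)
  set.seed(6)
  for (r in 1:10) {
    u <- rnorm(400); v <- cumsum(rnorm(400))
    expect_gte(transfer_entropy(u, v), 0)
  }
  expect_error(transfer_entropy(rnorm(100), rnorm(99)), "equal length")
  expect_error(transfer_entropy(rep(1, 100), rnorm(100)), "constant")
})

test_that("knn and gaussian transfer entropy agree on the Gaussian pair", {
  p <- ar_pair(a = 1, n = 4000, seed = 7)
  te_g <- transfer_entropy(p$x, p$y)
  te_k <- transfer_entropy(p$x, p$y, estimator_spec("knn"))
  expect_lt(abs(te_k - te_g) / te_g, 0.15)
})

test_that("causation entropy separates direct from mediated influence", {
  p <- ar_pair(a = 0.7, n = 8000, seed = 8)
  expect_identical(causation_entropy(p$x, p$y, NULL),
                   transfer_entropy(p$x, p$y))

  ch <- chain_xzy(50000, seed = 9)
  expect_gt(transfer_entropy(ch$x, ch$y), 0.05)
  expect_lte(causation_entropy(ch$x, ch$y, ch$z), 0.005)

  expect_equal(causation_entropy(p$x, p$y, p$x), 0)
})

test_that("pairwise causation matrix is near zero for independent players", {
  set.seed(10)
  th <- matrix(rnorm(4000 * 4), ncol = 4)
  w <- pairwise_causation_matrix(th, diff_phases = FALSE)
  expect_true(all(w$w <= 0.01))
  expect_equal(diag(w$w), rep(0, 4), ignore_attr = TRUE)
})

test_that("a planted hub driver dominates the causation matrix", {
  set.seed(11)
  n <- 5000
  hub <- as.numeric(stats::arima.sim(list(ar = 0.5), n))
  leaves <- sapply(1:4, function(j) 0.5 * c(0, hub[-n]) + rnorm(n))
  x <- cbind(hub, leaves)
  w <- pairwise_causation_matrix(x, diff_phases = FALSE)$w
  hub_min <- min(w[1, -1])
  other_max <- max(w[-1, ])
  expect_gt(hub_min, other_max)

  perm <- c(3, 5, 1, 2, 4)
  wp <- pairwise_causation_matrix(x[, perm], diff_phases = FALSE)$w
  expect_equal(unname(wp), unname(w[perm, perm]), tolerance = 1e-10)
})

test_that("net causation scores are flow differences summing to zero", {
  expect_equal(net_causation(matrix(0, 4, 4))$net, rep(0, 4))
  w <- matrix(0, 3, 3); w[1, 2] <- 0.2; w[1, 3] <- 0.1
  nc <- net_causation(w)
  expect_equal(nc$net, c(0.3, -0.2, -0.1))
  expect_equal(nc$influence_leader, 1L)

  set.seed(12)
  for (r in 1:10) {
    m <- matrix(abs(rnorm(49)), 7, 7); diag(m) <- 0
    expect_lt(abs(sum(net_causation(m)$net)), 1e-12)
  }
  bad <- diag(1, 3)
  expect_error(net_causation(bad), "diagonal")
})

test_that("oCSE recovers a small chain and controls false discoveries", {
  # 3-node chain 1 -> 2 -> 3
  A <- diag(0.3, 3); A[2, 1] <- 0.6; A[3, 2] <- 0.6
  hits <- sapply(1:3, function(s) {
    x <- sim_var(A, 3000, seed = 200 + s)
    par <- ocse_discover(x, estimator_spec(seed = s), diff_phases = FALSE)
    identical(par, list(integer(0), 1L, 2L))
  })
  expect_true(all(hits))

  # determinism for a fixed estimator seed
  x <- sim_var(A, 2000, seed = 300)
  p1 <- ocse_discover(x, estimator_spec(seed = 4), diff_phases = FALSE)
  p2 <- ocse_discover(x, estimator_spec(seed = 4), diff_phases = FALSE)
  expect_identical(p1, p2)

  # independent players: per-target false-parent rate stays near alpha
  set.seed(13)
  false_targets <- sapply(1:10, function(s) {
    y <- matrix(rnorm(600 * 5), ncol = 5)
    sum(lengths(ocse_discover(y, estimator_spec(seed = s),
                              diff_phases = FALSE)) > 0)
  })
  expect_lte(sum(false_targets) / 50, 0.1)
})
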