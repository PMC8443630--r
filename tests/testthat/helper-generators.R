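# Shared fixture generators (all built in code at test time).

# Stationary VAR(1): x_t = A x_{t-1} + e_t. A[j, i] != 0 means i -> j.
sim_var <- function(A, n, sd = 1, seed = 1, burn = 100) {
  set.seed(seed)
  p <- nrow(A)
  x <- matrix(0, n + burn, p)
  e <- matrix(rnorm((n + burn) * p, sd = sd), n + burn, p)
  for (t in 2:(n + burn)) x[t, ] <- A %*% x[t - 1, ] + e[t, ]
  x[(burn + 1):(burn + n), , drop = FALSE]
}

# Driven Gaussian pair: y_t = a * x_{t-1} + eps_t, x white N(0,1).
# Population transfer entropy x->y at lag 1 is 0.5 * log(1 + a^2 / sd_eps^2).
ar_pair <- function(a, n, sd_eps = 1, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- a * c(0, x[-n]) + rnorm(n, sd = sd_eps)
  list(x = x, y = y)
}

# Mediated chain x -> z -> y with autocorrelated source, so that at lag 1
# the x -> y flow is present but fully explained by z's past.
chain_xzy <- function(n, seed = 1) {
  set.seed(seed)
  x <- as.numeric(stats::arima.sim(list(ar = 0.7), n))
  z <- 0.8 * c(0, x[-n]) + rnorm(n)
  y <- 0.8 * c(0, z[-n]) + rnorm(n)
  list(x = x, y = y, z = z)
}

# Five-node linear benchmark with 6 true directed edges, coupling 0.5.
benchmark5 <- function() {
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 3), c(2, 5))
  A <- diag(0.3, 5)
  for (k in seq_len(nrow(edges))) A[edges[k, 2], edges[k, 1]] <- 0.5
  list(A = A, edges = edges,
       edge_keys = paste(edges[, 1], edges[, 2]))
}

discovered_edges <- function(parents) {
  unlist(lapply(seq_along(parents), function(j)
    if (length(parents[[j]])) paste(parents[[j]], j) else character(0)))
}

# Brute-force leadership index straight from the set definition.
brute_H <- function(th_row) {
  n <- length(th_row)
  vapply(seq_len(n), function(i)
    1L + sum(th_row[i] - th_row[-i] <= 0), integer(1))
}
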