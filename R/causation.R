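#' Estimator specification for information-flow measures
#'
#' Bundles the choices shared by all entropy-based estimators: the estimation
#' method, the lag, and the surrogate-test parameters used by
#' \code{\link{ocse_discover}}.
#'
#' @param method \code{"gaussian"} (closed-form conditional entropies from
#'   covariance determinants; the default, robust at a few hundred to a few
#'   thousand samples) or \code{"knn"} (Kozachenko--Leonenko nearest-neighbour
#'   entropies; nonparametric, heavier).
#' @param k_neighbors Neighbour count for the knn method.
#' @param tau Lag (samples) between past and present in transfer/causation
#'   entropy.
#' @param alpha Significance level for the surrogate (shuffle) test.
#' @param n_permutations Number of circular-shift surrogates (at least 19).
#' @param seed RNG seed for surrogate generation.
#' @return An object of class \code{"estimator_spec"}.
#' @export
estimator_spec <- function(method = c("gaussian", "knn"), k_neighbors = 4L,
                           tau = 1L, alpha = 0.05, n_permutations = 100L,
                           seed = 1L) {
  method <- match.arg(method)
  if (tau < 1L) stop("'tau' must be at least 1 sample")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (n_permutations < 19L) stop("'n_permutations' must be at least 19")
  structure(list(method = method, k_neighbors = as.integer(k_neighbors),
                 tau = as.integer(tau), alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "estimator_spec")
}

# log-determinant of the sample covariance of the columns of m
.logdet_cov <- function(m) {
  s <- stats::cov(m)
  ld <- determinant(s, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus))
    stop("singular or non-positive-definite sample covariance")
  as.numeric(ld$modulus)
}

.gaussian_entropy <- function(m) {
  d <- ncol(m)
  0.5 * (d * log(2 * pi * exp(1)) + .logdet_cov(m))
}

# Kozachenko-Leonenko differential entropy with Euclidean distances,
# brute-force neighbour search in row chunks (O(n^2); fine for moderate n).
.knn_entropy <- function(m, k) {
  n <- nrow(m)
  d <- ncol(m)
  if (n <= k) stop("need more samples than neighbours")
  rs <- rowSums(m^2)
  eps <- numeric(n)
  chunk <- max(1L, floor(2e6 / n))
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- outer(rs[rows], rs, "+") - 2 * m[rows, , drop = FALSE] %*% t(m)
    d2[cbind(seq_along(rows), rows)] <- Inf
    eps[rows] <- sqrt(pmax(apply(d2, 1L, function(v) sort(v, partial = k)[k]),
                           0))
  }
  if (any(eps == 0))
    stop("duplicate points: k-NN entropy estimate is degenerate")
  log_vd <- (d / 2) * log(pi) - lgamma(d / 2 + 1)
  digamma(n) - digamma(k) + log_vd + d * mean(log(eps))
}

#' Differential Shannon entropy of a sample
#'
#' Estimates the entropy (nats) of the distribution that generated
#' \code{samples}. The gaussian method returns
#' \eqn{\frac12 \ln((2\pi e)^d \det\hat\Sigma)}; the knn method the
#' Kozachenko--Leonenko nearest-neighbour estimate.
#'
#' @param samples Numeric vector (1-D) or matrix (observations in rows).
#' @param estimator An \code{\link{estimator_spec}}.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(samples, estimator = estimator_spec()) {
  m <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1L)
  if (nrow(m) < 10L * ncol(m))
    stop("need at least 10 samples per dimension")
  switch(estimator$method,
         gaussian = .gaussian_entropy(m),
         knn = .knn_entropy(m, estimator$k_neighbors))
}

# Conditional-entropy difference shared by transfer and causation entropy:
#   H(Y | W) - H(Y | X, W) with W the conditioning block.
# Computed as H(Y,W) - H(W) - H(Y,X,W) + H(X,W); clipped at zero because the
# population quantity is nonnegative while finite-sample estimates may dip
# below it.
.cond_flow <- function(y_now, x_past, w_past, estimator) {
  w_past <- as.matrix(w_past)
  hfun <- switch(estimator$method,
                 gaussian = .gaussian_entropy,
                 knn = function(m) .knn_entropy(m, estimator$k_neighbors))
  # a source already determined by the conditioning block carries no extra
  # information; detect (near-)linear dependence to avoid singular covariances
  res <- stats::lm.fit(cbind(1, w_past), x_past)$residuals
  if (stats::var(res) < 1e-12 * stats::var(x_past)) return(0)
  yw <- cbind(y_now, w_past)
  xw <- cbind(x_past, w_past)
  val <- hfun(yw) - hfun(w_past) - hfun(cbind(y_now, xw)) + hfun(xw)
  max(val, 0)
}

.lag_pair <- function(v, tau) {
  n <- length(v)
  list(now = v[(tau + 1L):n], past = v[1L:(n - tau)])
}

#' Causation entropy between two series given conditioning series
#'
#' Estimates \eqn{C_{X \to Y | (Y, Z)} = H(Y_t | Y_{t-\tau}, Z_{t-\tau}) -
#' H(Y_t | X_{t-\tau}, Y_{t-\tau}, Z_{t-\tau})}: the information flowing
#' directly from X to Y beyond what Y's own past and the conditioning set Z
#' already convey. With empty Z this reduces exactly to the transfer entropy.
#' Estimates are clipped at zero (the population quantity is nonnegative).
#'
#' @param x Source series (numeric vector).
#' @param y Target series, same length.
#' @param z Optional conditioning series: numeric vector or matrix
#'   (columns = series); \code{NULL} for none.
#' @param estimator An \code{\link{estimator_spec}}.
#' @return Estimated causation entropy in nats (nonnegative).
#' @export
causation_entropy <- function(x, y, z = NULL, estimator = estimator_spec()) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant series")
  zmat <- zmat_from(z)
  if (!is.null(zmat) && nrow(zmat) != length(y))
    stop("conditioning series must match the length of 'x' and 'y'")
  tau <- estimator$tau
  dim_total <- 3L + if (is.null(zmat)) 0L else ncol(zmat)
  if (length(y) - tau < 10L * dim_total)
    stop("series too short for the conditioning dimension")
  yl <- .lag_pair(y, tau)
  xl <- .lag_pair(x, tau)
  w <- yl$past
  if (!is.null(zmat))
    w <- cbind(w, zmat[1L:(length(y) - tau), , drop = FALSE])
  .cond_flow(yl$now, xl$past, w, estimator)
}

zmat_from <- function(z) {
  if (is.null(z)) return(NULL)
  m <- if (is.matrix(z)) z else matrix(z, ncol = 1L)
  if (ncol(m) == 0L) NULL else m
}

#' Transfer entropy between two series
#'
#' Estimates \eqn{T_{X \to Y} = H(Y_t | Y_{t-\tau}) -
#' H(Y_t | X_{t-\tau}, Y_{t-\tau})}, the uncertainty about Y's next state
#' removed by knowing X's current state beyond Y's own past; the special case
#' of \code{\link{causation_entropy}} with no conditioning set.
#'
#' @inheritParams causation_entropy
#' @return Estimated transfer entropy in nats (nonnegative).
#' @export
transfer_entropy <- function(x, y, estimator = estimator_spec()) {
  causation_entropy(x, y, NULL, estimator)
}

# Analysis series for the information-flow estimators: first differences of
# the unwrapped phases (an instantaneous-frequency proxy). Raw phases carry a
# deterministic linear trend that violates stationarity.
.analysis_series <- function(theta, diff_phases) {
  th <- if (inherits(theta, "phase_matrix")) theta$theta else as.matrix(theta)
  if (diff_phases) diff(th) else th
}

#' Pairwise causation-entropy matrix
#'
#' Computes the directed influence weight \eqn{w_{ij}} from every player i to
#' every player j. In \code{"full_conditioning"} mode (the default),
#' \eqn{w_{ij} = C_{i \to j | (j, P \setminus \{i, j\})}} with P the player
#' set, so every other player is conditioned out. In \code{"ocse"} mode the
#' conditioning set is player j's parent set discovered by
#' \code{\link{ocse_discover}} (minus i). Estimation runs on first
#' differences of the unwrapped phases unless \code{diff_phases = FALSE}.
#'
#' @param theta A \code{\link{phase_matrix}} or phase matrix (instants in
#'   rows).
#' @param estimator An \code{\link{estimator_spec}}.
#' @param mode \code{"full_conditioning"} or \code{"ocse"}.
#' @param diff_phases Use phase first differences (recommended).
#' @return An object of class \code{"causation_matrix"}: list with the
#'   \code{N x N} weight matrix \code{w} (nats, zero diagonal), \code{mode},
#'   \code{parents} (ocse mode), and the \code{estimator}.
#' @export
pairwise_causation_matrix <- function(theta, estimator = estimator_spec(),
                                      mode = c("full_conditioning", "ocse"),
                                      diff_phases = TRUE) {
  mode <- match.arg(mode)
  s <- .analysis_series(theta, diff_phases)
  n <- ncol(s)
  if (n < 2L) stop("need at least 2 players")
  parents <- NULL
  if (mode == "ocse")
    parents <- ocse_discover(theta, estimator, diff_phases = diff_phases)
  w <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)[-j]) {
      zidx <- if (mode == "full_conditioning") setdiff(seq_len(n), c(i, j))
              else setdiff(parents[[j]], i)
      z <- if (length(zidx)) s[, zidx, drop = FALSE] else NULL
      w[i, j] <- causation_entropy(s[, i], s[, j], z, estimator)
    }
  }
  pid <- colnames(s)
  dimnames(w) <- list(pid, pid)
  structure(list(w = w, mode = mode, parents = parents,
                 estimator = estimator, diff_phases = diff_phases),
            class = "causation_matrix")
}

#' @export
print.causation_matrix <- function(x, ...) {
  cat(sprintf("<causation_matrix: %d players, mode=%s, method=%s, tau=%d>\n",
              ncol(x$w), x$mode, x$estimator$method, x$estimator$tau))
  print(round(x$w, 4))
  invisible(x)
}

# Circular-shift surrogate significance test: rotating the source series
# destroys its cross-dependence with the target while preserving its
# autocorrelation. Returns the permutation p-value of the observed flow.
.surrogate_pvalue <- function(src, y, z, estimator) {
  obs <- causation_entropy(src, y, z, estimator)
  n <- length(src)
  shifts <- sample(seq(estimator$tau + 5L, n - estimator$tau - 5L),
                   estimator$n_permutations, replace = TRUE)
  exceed <- vapply(shifts, function(m) {
    rot <- src[((seq_len(n) + m - 1L) %% n) + 1L]
    causation_entropy(rot, y, z, estimator) >= obs
  }, logical(1))
  list(p = (1 + sum(exceed)) / (estimator$n_permutations + 1), obs = obs)
}

#' Optimal causation entropy (oCSE) parent discovery
#'
#' Discovers each player's direct sources in two stages. Forward
#' (aggregative): greedily add the candidate source with the largest
#' causation entropy given the current parent set, as long as a circular-shift
#' surrogate test rejects independence at level \code{alpha}. Backward
#' (progressive pruning): remove any parent whose contribution conditioned on
#' the remaining parents fails the same test. Deterministic for a fixed
#' \code{estimator$seed}.
#'
#' @inheritParams pairwise_causation_matrix
#' @return A list of integer vectors: element j holds the discovered parent
#'   indices of player j (possibly empty).
#' @export
ocse_discover <- function(theta, estimator = estimator_spec(),
                          diff_phases = TRUE) {
  s <- .analysis_series(theta, diff_phases)
  n <- ncol(s)
  if (n < 2L) return(rep(list(integer(0)), max(n, 1L)))
  set.seed(estimator$seed)
  lapply(seq_len(n), function(j) {
    y <- s[, j]
    parents <- integer(0)
    candidates <- setdiff(seq_len(n), j)
    # forward aggregative stage
    repeat {
      remaining <- setdiff(candidates, parents)
      if (!length(remaining)) break
      z <- if (length(parents)) s[, parents, drop = FALSE] else NULL
      ce <- vapply(remaining, function(i)
        causation_entropy(s[, i], y, z, estimator), numeric(1))
      best <- remaining[which.max(ce)]
      test <- .surrogate_pvalue(s[, best], y, z, estimator)
      # Bonferroni over the candidates screened: the tested flow is the
      # maximum of length(remaining) estimates, so its nominal p-value is
      # selection-biased
      if (test$p > estimator$alpha / length(remaining)) break
      parents <- c(parents, best)
    }
    # backward pruning stage
    for (p in rev(parents)) {
      others <- setdiff(parents, p)
      z <- if (length(others)) s[, others, drop = FALSE] else NULL
      test <- .surrogate_pvalue(s[, p], y, z, estimator)
      if (test$p > estimator$alpha) parents <- others
    }
    sort(parents)
  })
}

#' Net causation-entropy score
#'
#' Summarizes a causation matrix into each player's net information outflow
#' \eqn{NetCaus_i = \delta_{i,out} - \delta_{i,in}}, where
#' \eqn{\delta_{i,out} = \sum_{j \ne i} w_{ij}} and
#' \eqn{\delta_{i,in} = \sum_{j \ne i} w_{ji}}. The influence leader is the
#' player maximizing NetCaus. The scores always sum to zero.
#'
#' @param w A \code{\link{pairwise_causation_matrix}} result or a square
#'   numeric matrix with zero diagonal.
#' @return An object of class \code{"netflow"}: list with \code{net},
#'   \code{delta_out}, \code{delta_in} and \code{influence_leader}.
#' @export
net_causation <- function(w) {
  m <- if (inherits(w, "causation_matrix")) w$w else as.matrix(w)
  if (nrow(m) != ncol(m)) stop("'w' must be square")
  if (any(diag(m) != 0)) stop("'w' must have a zero diagonal")
  delta_out <- rowSums(m)
  delta_in <- colSums(m)
  net <- delta_out - delta_in
  structure(list(net = net, delta_out = delta_out, delta_in = delta_in,
                 influence_leader = which.max(net)),
            class = "netflow")
}

#' @export
print.netflow <- function(x, ...) {
  cat("<netflow> NetCaus per player:\n")
  print(round(x$net, 4))
  cat("influence leader: player", x$influence_leader, "\n")
  invisible(x)
}
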