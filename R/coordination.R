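#' Kuramoto (cluster-phase) order parameter
#'
#' At each instant computes the modulus of the mean unit phasor,
#' \eqn{z(t_k) = |\frac{1}{N}\sum_i e^{\mathrm{i}\theta_i(t_k)}|}: 1 when all
#' players are perfectly overlapped in phase, 0 for balanced phase
#' opposition. The trial-level coordination measure is the time average
#' \eqn{\bar z}.
#'
#' @param theta A \code{\link{phase_matrix}} or numeric phase matrix
#'   (instants in rows, players in columns).
#' @return An object of class \code{"order_parameter"}: list with the series
#'   \code{z} and the mean \code{z_bar}.
#' @export
order_parameter <- function(theta) {
  th <- if (inherits(theta, "phase_matrix")) theta$theta else as.matrix(theta)
  if (nrow(th) == 0L || ncol(th) < 2L) stop("need phases for at least 2 players")
  z <- Mod(rowMeans(exp(1i * th)))
  structure(list(z = z, z_bar = mean(z)), class = "order_parameter")
}

#' @export
print.order_parameter <- function(x, ...) {
  cat(sprintf("<order_parameter: z_bar = %.4f over %d instants>\n",
              x$z_bar, length(x$z)))
  invisible(x)
}

#' Chi-squared goodness-of-fit test
#'
#' \eqn{\chi^2 = \sum (O - E)^2 / E} with \code{df = cells - 1} and an
#' upper-tail p-value. \code{expected} may be counts or probabilities
#' (probabilities are scaled to the observed total).
#'
#' @param observed Observed counts.
#' @param expected Expected counts or probabilities (all positive).
#' @return A \code{"test_result"} list: \code{statistic}, \code{df},
#'   \code{p_value}, \code{observed}, \code{expected}.
#' @export
chi_square_gof <- function(observed, expected) {
  if (sum(observed) <= 0) stop("observed counts must sum to a positive total")
  if (any(expected <= 0)) stop("expected values must be positive")
  if (length(expected) != length(observed))
    stop("'observed' and 'expected' must have equal length")
  if (abs(sum(expected) - 1) < 1e-8) expected <- expected * sum(observed)
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = observed, expected = expected,
                 method = "chi-squared goodness of fit"),
            class = "test_result")
}

#' Independent two-sample t-test (pooled variance)
#'
#' Student's t-test with pooled variance and \code{df = n_a + n_b - 2},
#' two-sided p-value, plus Cohen's d on the same pooled SD.
#'
#' @param a,b Numeric samples (each at least 2 values).
#' @return A \code{"test_result"} list: \code{statistic} (t), \code{df},
#'   \code{p_value}, \code{effect_size} (Cohen's d) and per-group
#'   \code{summaries}.
#' @export
independent_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each sample needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("zero pooled variance")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2L
  structure(list(statistic = t, df = df,
                 p_value = 2 * stats::pt(-abs(t), df),
                 effect_size = (mean(a) - mean(b)) / sqrt(sp2),
                 summaries = data.frame(
                   group = c("a", "b"), mean = c(mean(a), mean(b)),
                   sd = c(stats::sd(a), stats::sd(b)), n = c(na, nb)),
                 method = "independent t-test (pooled)"),
            class = "test_result")
}

#' Cohen's d effect size
#'
#' Standardized mean difference using the pooled standard deviation with
#' \code{n - 1} weights, consistent with \code{\link{independent_t_test}}.
#'
#' @param a,b Numeric samples.
#' @return Cohen's d.
#' @export
cohens_d <- function(a, b) {
  cohens_d_summary(mean(a), stats::sd(a), length(a),
                   mean(b), stats::sd(b), length(b))
}

#' Cohen's d from group summaries
#'
#' @param m1,s1,n1 Mean, SD and size of the first group.
#' @param m2,s2,n2 Mean, SD and size of the second group.
#' @return Cohen's d.
#' @export
cohens_d_summary <- function(m1, s1, n1, m2, s2, n2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (m1 - m2) / sp
}

#' One-way ANOVA with eta-squared effect size
#'
#' Classical between/within decomposition:
#' \eqn{F = MS_{between} / MS_{within}} with df \eqn{(k-1, n-k)} and
#' \eqn{\eta^2 = SS_{between} / SS_{total}}.
#'
#' @param groups List of numeric samples (at least 2 groups, each with at
#'   least 2 values).
#' @return A \code{"test_result"} list: \code{statistic} (F), \code{df}
#'   (pair), \code{p_value}, \code{effect_size} (eta-squared), group
#'   \code{summaries}.
#' @export
one_way_anova <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 values")
  all_x <- unlist(groups)
  n <- length(all_x)
  gm <- mean(all_x)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0) stop("zero within-group variance")
  df1 <- k - 1L; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  structure(list(statistic = f, df = c(df1, df2),
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 effect_size = ssb / (ssb + ssw),
                 summaries = data.frame(
                   group = seq_len(k),
                   mean = vapply(groups, mean, numeric(1)),
                   sd = vapply(groups, stats::sd, numeric(1)),
                   n = vapply(groups, length, integer(1))),
                 method = "one-way ANOVA"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  df <- paste(x$df, collapse = ", ")
  cat(sprintf("<test_result: %s; statistic = %.4f, df = %s, p = %.4g%s>\n",
              x$method, x$statistic, df, x$p_value,
              if (!is.null(x$effect_size))
                sprintf(", effect = %.4f", x$effect_size) else ""))
  invisible(x)
}

#' D'Agostino--Pearson omnibus normality test
#'
#' Combines z-transformed sample skewness and kurtosis into
#' \eqn{K^2 = Z_{g1}^2 + Z_{g2}^2}, referred to a chi-squared distribution
#' with 2 df. Requires at least 8 observations.
#'
#' @param x Numeric sample.
#' @return A \code{"test_result"} list with \code{statistic} (K-squared),
#'   \code{df = 2} and \code{p_value}.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8L) stop("need at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2
  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)
  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  base <- (1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4)))
  z2 <- ((1 - 2 / (9 * a)) - sign(base) * abs(base)^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  structure(list(statistic = k2, df = 2L,
                 p_value = stats::pchisq(k2, 2, lower.tail = FALSE),
                 method = "D'Agostino-Pearson omnibus"),
            class = "test_result")
}
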