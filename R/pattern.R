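#' Classify a trial into a leadership pattern
#'
#' Combines the mean phase leadership index and the net causation-entropy
#' score. With the default orientation (small \eqn{\bar H} = phase leader),
#' let L be the phase leader (argmin \eqn{\bar H}), G the phase laggard
#' (argmax), and M1, M2 the two players with the largest NetCaus. The trial is
#' \describe{
#'   \item{P3}{if \{M1, M2\} = \{L, G\} and their NetCaus values are similar
#'     (gap at most \code{p3_tolerance} of the larger): shared leadership;}
#'   \item{P1}{else if M1 = L: the phase leader is the influence leader
#'     ("the fastest leads");}
#'   \item{P2}{else if M1 = G: the phase laggard is the influence leader
#'     ("the slowest leads");}
#'   \item{NONE}{otherwise.}
#' }
#' Exact ties in argmin/argmax are broken toward the lower player index and
#' flagged in the evidence.
#'
#' @param h_bar Numeric vector of mean phase leadership indices.
#' @param net A \code{\link{net_causation}} result or numeric NetCaus vector.
#' @param p3_tolerance Relative NetCaus gap below which the top two flows
#'   count as "similar" (default 0.2).
#' @param orientation \code{"index"} (default; small \eqn{\bar H} leads, as
#'   the index equations imply) or \code{"prose"} (flipped).
#' @return An object of class \code{"pattern_result"}: list with
#'   \code{label}, \code{influence_leader} (index, or pair for P3),
#'   \code{phase_leader}, \code{phase_laggard}, \code{tolerance_used} and an
#'   \code{evidence} list with the extremal values.
#' @export
classify_trial <- function(h_bar, net, p3_tolerance = 0.2,
                           orientation = c("index", "prose")) {
  orientation <- match.arg(orientation)
  nv <- if (inherits(net, "netflow")) net$net else as.numeric(net)
  n <- length(h_bar)
  if (length(nv) != n) stop("'h_bar' and 'net' must have equal length")
  if (n < 3L) stop("need at least 3 players")
  if (diff(range(h_bar)) == 0) stop("all-equal mean leadership indices")
  leader <- which.min(h_bar)
  laggard <- which.max(h_bar)
  if (orientation == "prose") { tmp <- leader; leader <- laggard; laggard <- tmp }
  ord <- order(nv, decreasing = TRUE)
  m1 <- ord[1L]; m2 <- ord[2L]
  tied <- sum(h_bar == h_bar[leader]) > 1L || sum(h_bar == h_bar[laggard]) > 1L ||
    sum(nv == nv[m1]) > 1L
  gap <- nv[m1] - nv[m2]
  label <-
    if (setequal(c(m1, m2), c(leader, laggard)) &&
        gap <= p3_tolerance * abs(nv[m1])) "P3"
    else if (m1 == leader) "P1"
    else if (m1 == laggard) "P2"
    else "NONE"
  structure(list(
    label = label,
    influence_leader = if (label == "P3") sort(c(m1, m2)) else m1,
    phase_leader = leader, phase_laggard = laggard,
    tolerance_used = p3_tolerance,
    evidence = list(h_bar_min = h_bar[leader], h_bar_max = h_bar[laggard],
                    netcaus_top = nv[m1], netcaus_second = nv[m2],
                    netcaus_gap = gap, ties = tied)),
    class = "pattern_result")
}

#' @export
print.pattern_result <- function(x, ...) {
  cat(sprintf("<pattern_result: %s; influence leader %s; phase leader %d, laggard %d>\n",
              x$label, paste(x$influence_leader, collapse = "+"),
              x$phase_leader, x$phase_laggard))
  invisible(x)
}

#' Pooled pattern frequencies
#'
#' @param results List of \code{\link{classify_trial}} results (or a
#'   character vector of labels).
#' @return List with per-label \code{counts}, \code{fractions}, the number of
#'   trials and the fraction of trials in which any of the three patterns
#'   emerged.
#' @export
pattern_frequencies <- function(results) {
  labels <- if (is.character(results)) results
            else vapply(results, function(r) r$label, character(1))
  if (!length(labels)) stop("no trials")
  lv <- c("P1", "P2", "P3", "NONE")
  counts <- table(factor(labels, levels = lv))
  list(counts = counts, fractions = counts / length(labels),
       n_trials = length(labels),
       any_pattern = sum(counts[c("P1", "P2", "P3")]) / length(labels))
}

#' Chance frequency of leadership-pattern emergence
#'
#' Probability, under a uniformly random assignment of phase ranks, that the
#' single most influential player lands on one of the two extreme ranks (the
#' event underlying all three patterns): \code{2 / n_players}. For seven
#' players this is 28.57\%.
#'
#' @param n_players Group size (at least 3).
#' @return The chance fraction.
#' @export
chance_pattern_frequency <- function(n_players) {
  if (n_players < 3) stop("'n_players' must be at least 3")
  2 / n_players
}

#' Residual-based outlier removal for scatter fits
#'
#' Fits an initial polynomial of the requested degree and drops points whose
#' absolute residual exceeds 3 times the median absolute deviation of the
#' residuals, removing at most \code{floor(n/10)} points (worst offenders
#' first). Deterministic.
#'
#' @param x,y Numeric coordinate vectors (at least 4 points).
#' @param degree Degree of the screening fit (1 or 2).
#' @return List with retained \code{x}, \code{y}, the \code{removed} count
#'   and the removed indices \code{which}.
#' @export
remove_outliers <- function(x, y, degree = 1L) {
  n <- length(x)
  if (n < 4L || length(y) != n) stop("need at least 4 (x, y) pairs")
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  r <- abs(stats::residuals(fit))
  # floor guards against flagging numerical noise on (near-)exact fits
  thresh <- max(3 * stats::mad(r, center = stats::median(r)),
                1e-8 * (diff(range(y)) + 1))
  cap <- floor(n / 10)
  bad <- unname(which(r > thresh))
  if (length(bad) > cap) bad <- bad[order(r[bad], decreasing = TRUE)][seq_len(cap)]
  keep <- setdiff(seq_len(n), bad)
  list(x = x[keep], y = y[keep], removed = length(bad), which = sort(bad))
}

#' Polynomial characterization of a leadership pattern
#'
#' Ordinary least-squares fit of NetCaus against the mean phase leadership
#' index for the trials of one pattern: degree 1 (linear, with Pearson r) for
#' the single-leader patterns, degree 2 (parabolic) for shared leadership,
#' where influence peaks at both phase extremes. Reports the fit F-test
#' p-value and a residual-normality check (D'Agostino--Pearson omnibus).
#'
#' @param x Predictor values (mean phase leadership indices).
#' @param y Response values (NetCaus scores).
#' @param degree 1 or 2.
#' @param trim_outliers Apply \code{\link{remove_outliers}} first.
#' @return An object of class \code{"regression_fit"}: list with
#'   \code{degree}, \code{coefficients}, \code{pearson_r} (degree 1),
#'   \code{r_squared}, \code{p_value}, \code{residual_normality_p},
#'   \code{n_points}, \code{outliers_removed}.
#' @export
characterize_pattern <- function(x, y, degree = 1L, trim_outliers = TRUE) {
  degree <- as.integer(degree)
  if (!degree %in% c(1L, 2L)) stop("'degree' must be 1 or 2")
  if (length(x) < degree + 2L) stop("too few points for the requested degree")
  if (diff(range(x)) == 0) stop("degenerate design: all x equal")
  removed <- 0L
  if (trim_outliers && length(x) >= 4L) {
    cl <- remove_outliers(x, y, degree)
    x <- cl$x; y <- cl$y; removed <- cl$removed
  }
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  sm <- summary(fit)
  pval <- if (sm$sigma == 0) 0
          else unname(stats::pf(sm$fstatistic[1L], sm$fstatistic[2L],
                                sm$fstatistic[3L], lower.tail = FALSE))
  resid_p <- tryCatch(dagostino_pearson(stats::residuals(fit))$p_value,
                      error = function(e) NA_real_)
  structure(list(degree = degree,
                 coefficients = unname(stats::coef(fit)),
                 pearson_r = if (degree == 1L) stats::cor(x, y) else NA_real_,
                 r_squared = sm$r.squared,
                 p_value = pval,
                 residual_normality_p = resid_p,
                 n_points = length(x),
                 outliers_removed = removed),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit: degree %d, n=%d (%d outliers removed)>\n",
              x$degree, x$n_points, x$outliers_removed))
  cat(sprintf("  R^2 = %.4f, p = %.3g%s\n", x$r_squared, x$p_value,
              if (!is.na(x$pearson_r)) sprintf(", Pearson r = %.4f", x$pearson_r)
              else ""))
  invisible(x)
}

#' Pattern occurrence across topologies
#'
#' Tabulates pattern vs no-pattern trials per topology and tests whether
#' patterned trials are uniformly distributed over the topologies with a
#' chi-squared goodness-of-fit test. Cells with expected count below 1 raise
#' a warning.
#'
#' @param results List of \code{\link{classify_trial}} results (or label
#'   vector).
#' @param topologies Character vector of per-trial topology labels.
#' @return List with the \code{table} (topology x pattern/none) and the
#'   chi-squared \code{test} (a \code{\link{chi_square_gof}} result).
#' @export
pattern_by_topology <- function(results, topologies) {
  labels <- if (is.character(results)) results
            else vapply(results, function(r) r$label, character(1))
  if (length(labels) != length(topologies))
    stop("'results' and 'topologies' must have equal length")
  tops <- sort(unique(topologies))
  if (length(tops) < 2L) stop("need at least 2 topologies")
  patterned <- labels != "NONE"
  tab <- table(topology = topologies,
               outcome = factor(ifelse(patterned, "pattern", "none"),
                                levels = c("pattern", "none")))
  obs <- tab[, "pattern"]
  expected <- rep(sum(obs) / length(tops), length(tops))
  if (any(expected < 1))
    warning("expected counts below 1; chi-squared approximation is weak")
  test <- chi_square_gof(as.numeric(obs), expected)
  list(table = tab, test = test)
}
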