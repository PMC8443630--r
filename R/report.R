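#' Pooled leadership report over a batch of trials
#'
#' Fits \code{\link{leadership}} to every trial, then pools: pattern counts
#' and fractions, a chi-squared test of pattern occurrence against the chance
#' level \code{2 / N}, per-pattern polynomial characterizations of NetCaus
#' against \eqn{\bar H} (linear for P1/P2, parabolic for P3), a
#' pattern-by-topology table when several topologies are present, and the
#' coordination comparison (\eqn{\bar z} in patterned vs patternless trials,
#' pooled t-test with Cohen's d).
#'
#' @param trials List of \code{\link{trial_recording}}s (or
#'   \code{\link{phase_matrix}} objects).
#' @param ... Passed on to \code{\link{leadership}}.
#' @return An object of class \code{"leadership_report"}.
#' @export
leadership_report <- function(trials, ...) {
  if (!length(trials)) stop("need at least 1 trial")
  fits <- lapply(trials, leadership, ...)
  n_players <- length(fits[[1L]]$h_bar)
  if (any(vapply(fits, function(f) length(f$h_bar), integer(1)) != n_players))
    stop("all trials in a pooled report must have the same player count")
  labels <- vapply(fits, function(f) f$pattern$label, character(1))
  freq <- pattern_frequencies(labels)

  # chance null: the three patterns split 2/N equally, the rest is NONE
  q <- chance_pattern_frequency(n_players)
  probs <- c(P1 = q / 3, P2 = q / 3, P3 = q / 3, NONE = 1 - q)
  chance_test <- chi_square_gof(as.numeric(freq$counts), as.numeric(probs))

  fit_for <- function(lab, degree) {
    sel <- which(labels == lab)
    if (length(sel) < degree + 2L) return(NULL)
    xs <- unlist(lapply(fits[sel], function(f) f$h_bar))
    ys <- unlist(lapply(fits[sel], function(f) f$flows$net))
    characterize_pattern(xs, ys, degree = degree)
  }
  fits_by_pattern <- list(P1 = fit_for("P1", 1L), P2 = fit_for("P2", 1L),
                          P3 = fit_for("P3", 2L))

  z_bar <- vapply(fits, function(f) f$z_bar, numeric(1))
  patterned <- labels != "NONE"
  coordination <- if (sum(patterned) >= 2L && sum(!patterned) >= 2L)
    independent_t_test(z_bar[patterned], z_bar[!patterned]) else NULL

  topologies <- vapply(fits, function(f)
    if (is.null(f$topology)) NA_character_ else f$topology, character(1))
  by_topology <- if (length(unique(stats::na.omit(topologies))) >= 2L)
    pattern_by_topology(labels, topologies) else NULL

  structure(list(fits = fits, labels = labels, frequencies = freq,
                 chance_test = chance_test,
                 pattern_fits = fits_by_pattern,
                 z_bar = z_bar, coordination = coordination,
                 by_topology = by_topology, n_players = n_players),
            class = "leadership_report")
}

#' @export
print.leadership_report <- function(x, ...) {
  cat(sprintf("<leadership_report: %d trials, %d players>\n",
              x$frequencies$n_trials, x$n_players))
  print(x$frequencies$counts)
  cat(sprintf("any-pattern fraction: %.1f%% (chance %.2f%%)\n",
              100 * x$frequencies$any_pattern,
              100 * chance_pattern_frequency(x$n_players)))
  cat(sprintf("chi-squared vs chance: X2(%d) = %.2f, p = %.3g\n",
              x$chance_test$df, x$chance_test$statistic,
              x$chance_test$p_value))
  if (!is.null(x$coordination))
    cat(sprintf("z_bar pattern vs none: t(%d) = %.2f, p = %.3g, d = %.2f\n",
                x$coordination$df, x$coordination$statistic,
                x$coordination$p_value, x$coordination$effect_size))
  invisible(x)
}

#' Serialize a leadership report to JSON
#'
#' Writes a self-describing JSON document with per-trial indices and pooled
#' statistics. Deterministic inputs produce byte-identical files.
#'
#' @param report A \code{\link{leadership_report}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "leadership_report"))
  fit_json <- function(f) {
    if (is.null(f)) return(NULL)
    list(degree = f$degree, coefficients = f$coefficients,
         pearson_r = f$pearson_r, r_squared = f$r_squared,
         p_value = f$p_value,
         residual_normality_p = f$residual_normality_p,
         n_points = f$n_points, outliers_removed = f$outliers_removed)
  }
  test_json <- function(t) {
    if (is.null(t)) return(NULL)
    list(statistic = t$statistic, df = t$df, p_value = t$p_value,
         effect_size = t$effect_size)
  }
  doc <- list(
    schema = "leadsync-report/1",
    n_trials = report$frequencies$n_trials,
    n_players = report$n_players,
    trials = lapply(report$fits, function(f) list(
      h_bar = unname(f$h_bar), netcaus = unname(f$flows$net),
      w = unname(f$w$w), pattern = f$pattern$label, z_bar = f$z_bar,
      topology = f$topology)),
    pattern_counts = as.list(report$frequencies$counts),
    any_pattern_fraction = report$frequencies$any_pattern,
    chance_fraction = chance_pattern_frequency(report$n_players),
    chi_square_vs_chance = test_json(report$chance_test),
    pattern_fits = lapply(report$pattern_fits, fit_json),
    coordination_t_test = test_json(report$coordination))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 12,
                       null = "null")
  invisible(path)
}

#' Simulate a batch of ground-truthed trials
#'
#' Generates \code{n_trials} synthetic trials with the requested planted
#' pattern. One root seed fans out to per-trial seeds through a fixed stride,
#' so adding trials never perturbs earlier ones.
#'
#' @param pattern Planted pattern label.
#' @param n_trials Number of trials.
#' @param root_seed Root seed; trial t uses \code{root_seed + 10 * (t - 1)}.
#' @param topology_kind Topology name passed to \code{\link{make_topology}}.
#' @param n_players Group size.
#' @param ... Further arguments to \code{\link{oscillator_config}}.
#' @return List of \code{\link{trial_recording}}s with ground truth attached.
#' @export
simulate_batch <- function(pattern = "P1", n_trials = 10L, root_seed = 1L,
                           topology_kind = "complete", n_players = 7L, ...) {
  lapply(seq_len(n_trials), function(t) {
    seed <- root_seed + 10L * (t - 1L)
    cfg <- oscillator_config(topology = make_topology(topology_kind,
                                                      n_players),
                             seed = seed, ...)
    simulate_trial(plant_pattern(pattern, cfg))
  })
}
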