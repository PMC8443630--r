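#' Moving-average smoothing
#'
#' Replaces each channel by its running mean over a window of
#' \code{window} samples. The window is centred (for even windows, one more
#' trailing than leading sample) and shrinks at the series boundaries so the
#' output has the same length as the input.
#'
#' @param x A \code{\link{trial_recording}}.
#' @param window Window length in samples (default 10).
#' @return A smoothed \code{trial_recording}.
#' @export
moving_average <- function(x, window = 10L) {
  stopifnot(inherits(x, "trial_recording"))
  n <- nrow(x$positions)
  window <- as.integer(window)
  if (window < 1L) stop("'window' must be >= 1")
  if (window > n) stop("'window' exceeds series length")
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  idx <- seq_len(n)
  lo <- pmax(idx - left, 1L)
  hi <- pmin(idx + right, n)
  out <- apply(x$positions, 2L, function(col) {
    cs <- cumsum(c(0, col))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  y <- x
  y$positions <- out
  colnames(y$positions) <- x$player_ids
  y
}

#' Cubic-spline resampling to a higher rate
#'
#' Interpolates every channel with a cubic spline onto a uniform grid at
#' \code{fs_out}, spanning the original time range. Original sample instants
#' reproduce the original values exactly (splines interpolate their knots).
#'
#' @param x A \code{\link{trial_recording}}.
#' @param fs_out Target sampling rate (Hz), above \code{x$fs}.
#' @return The resampled \code{trial_recording} at \code{fs_out}.
#' @export
resample_spline <- function(x, fs_out = 100) {
  stopifnot(inherits(x, "trial_recording"))
  n <- nrow(x$positions)
  if (n < 4L) stop("need at least 4 samples for cubic-spline resampling")
  if (fs_out < x$fs) stop("'fs_out' must not be below the input rate")
  if (fs_out == x$fs) return(x)
  t_in <- (seq_len(n) - 1L) / x$fs
  t_out <- seq(0, t_in[n], by = 1 / fs_out)
  out <- apply(x$positions, 2L, function(col)
    stats::spline(t_in, col, xout = t_out, method = "fmm")$y)
  y <- trial_recording(out, fs = fs_out, player_ids = x$player_ids,
                       topology = x$topology, experiment = x$experiment)
  y$seed <- x$seed
  y$ground_truth <- x$ground_truth
  y
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Applies an order-\code{order} Butterworth low-pass filter forward and
#' backward (\code{signal::filtfilt}) so the net filter has zero phase and
#' unit DC gain. The default 6 Hz cutoff is twice the typical human natural
#' movement frequency (about 3 Hz).
#'
#' @param x A \code{\link{trial_recording}}.
#' @param cutoff Cutoff frequency (Hz), below Nyquist.
#' @param order Filter order (each pass).
#' @return The filtered \code{trial_recording}.
#' @export
butterworth_lowpass <- function(x, cutoff = 6, order = 4L) {
  stopifnot(inherits(x, "trial_recording"))
  if (cutoff <= 0 || cutoff >= x$fs / 2)
    stop("'cutoff' must lie strictly between 0 and the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (x$fs / 2), type = "low")
  # odd-reflection padding tames the start/end transients of the
  # forward-backward pass
  pad <- min(ceiling(20 * x$fs / cutoff), nrow(x$positions) - 1L)
  out <- apply(x$positions, 2L, function(col) {
    n <- length(col)
    ext <- c(2 * col[1] - col[(pad + 1):2],
             col,
             2 * col[n] - col[(n - 1):(n - pad)])
    signal::filtfilt(bf, ext)[(pad + 1):(pad + n)]
  })
  y <- x
  y$positions <- out
  colnames(y$positions) <- x$player_ids
  y
}

# Analytic signal via the frequency-domain construction: zero the negative
# frequencies, double the positive ones, keep DC (and Nyquist for even n).
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  jumps <- round(dp / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

#' Phase reconstruction by the Hilbert (analytic-signal) method
#'
#' For each channel: subtract the channel mean, form the analytic signal,
#' take its argument, and unwrap to a continuous phase. Channels must be
#' oscillatory (cross their mean at least twice).
#'
#' @param x A \code{\link{trial_recording}}.
#' @return A \code{\link{phase_matrix}} of unwrapped phases (rad).
#' @export
hilbert_phase <- function(x) {
  stopifnot(inherits(x, "trial_recording"))
  theta <- apply(x$positions, 2L, function(col) {
    centred <- col - mean(col)
    if (all(centred == 0)) stop("constant channel: phase undefined")
    s <- sign(centred)
    crossings <- sum(diff(s[s != 0]) != 0)
    if (crossings < 2)
      stop("channel is not oscillatory (fewer than 2 mean crossings)")
    unwrap_phase(Arg(analytic_signal(centred)))
  })
  phase_matrix(theta, fs = x$fs, source = "hilbert")
}

#' Trim transient samples at both ends of a phase matrix
#'
#' Drops a fraction of samples at each end, quarantining analytic-signal edge
#' effects before any downstream index is computed.
#'
#' @param phases A \code{\link{phase_matrix}}.
#' @param trim Fraction of samples removed at each end (default 0.05).
#' @return The trimmed \code{phase_matrix}.
#' @export
trim_phases <- function(phases, trim = 0.05) {
  stopifnot(inherits(phases, "phase_matrix"), trim >= 0, trim < 0.5)
  n <- nrow(phases$theta)
  cut <- floor(trim * n)
  keep <- (cut + 1L):(n - cut)
  phase_matrix(phases$theta[keep, , drop = FALSE], fs = phases$fs,
               source = paste0(phases$source, " + trim", trim))
}

#' Experiment-appropriate preprocessing chain
#'
#' Dispatches on the recording's \code{experiment} tag:
#' \describe{
#'   \item{pendula / synthetic}{10-sample moving average, then Hilbert phase
#'     (position data already sampled at the analysis rate).}
#'   \item{chronos}{cubic-spline resampling to 100 Hz, 6 Hz zero-phase
#'     Butterworth low-pass, then Hilbert phase.}
#' }
#' After phase extraction, \code{trim} of the samples at each end are
#' discarded (analytic-signal edge effects).
#'
#' @param x A \code{\link{trial_recording}}.
#' @param trim End-trim fraction applied to the phases.
#' @return A \code{\link{phase_matrix}}; its \code{source} records the chain.
#' @export
preprocess <- function(x, trim = 0.05) {
  stopifnot(inherits(x, "trial_recording"))
  chain <- switch(x$experiment,
    pendula = ,
    synthetic = {
      ph <- hilbert_phase(moving_average(x, 10L))
      ph$source <- "moving_average(10) + hilbert"
      ph
    },
    chronos = {
      ph <- hilbert_phase(butterworth_lowpass(resample_spline(x, 100), 6, 4L))
      ph$source <- "spline(100Hz) + butterworth(6Hz,4) + hilbert"
      ph
    },
    stop("unknown experiment tag: ", x$experiment))
  trim_phases(chain, trim)
}
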