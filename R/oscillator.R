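#' Configuration of the coupled phase-oscillator generator
#'
#' Parameterizes a group of Kuramoto-style phase oscillators used as a
#' ground-truthed surrogate for a group of people synchronizing an oscillatory
#' movement. Each player i obeys the stochastic phase equation
#' \deqn{d\theta_i = [\omega_i + s_i k \sum_j a_{ij} \sin(\theta_j - \theta_i)]\,dt
#'   + \sigma\, dW_i,}
#' where \code{a} is the visual-coupling adjacency, \code{k} the coupling gain,
#' and \code{s_i} the per-player multiplier on incoming coupling. A "stubborn"
#' player (\code{s_i} close to 0) largely ignores the others and thereby
#' becomes a net source of information for the group.
#'
#' Defaults emulate a 7-player pendulum-swinging group: natural frequencies
#' drawn uniformly around 1 Hz (2*pi*[0.9, 1.1] rad/s), coupling gain 2,
#' phase-diffusion intensity 0.3 rad/sqrt(s), 30 s trials sampled at 20 Hz.
#'
#' @param topology A \code{\link{make_topology}} object.
#' @param omega Natural frequencies (rad/s), one per player; if \code{NULL},
#'   drawn uniformly on \code{2*pi*omega_range} using \code{seed}.
#' @param omega_range Frequency band (Hz) for the default omega draw.
#' @param coupling_gain Scalar coupling gain k.
#' @param in_gain_scale Per-player multiplier in [0, 1] on incoming coupling;
#'   values much below 1 mark stubborn (leader) agents.
#' @param noise_sd Phase-diffusion intensity sigma (rad/sqrt(s)).
#' @param dt Internal integration step (s).
#' @param fs Trial sampling rate (Hz) to which the integration is decimated.
#' @param duration Trial length (s).
#' @param amplitude Position amplitude per player (arbitrary units).
#' @param obs_noise_sd Additive observation noise on positions.
#' @param init_phase Initial phases (rad); \code{NULL} draws them uniformly
#'   on [0, 2*pi).
#' @param seed Root RNG seed for the trial; the frequency draw uses
#'   \code{seed}, the integration noise \code{seed + 1}, observation noise
#'   \code{seed + 2}.
#' @return An object of class \code{"oscillator_config"}.
#' @export
oscillator_config <- function(topology = make_topology("complete", 7),
                              omega = NULL,
                              omega_range = c(0.9, 1.1),
                              coupling_gain = 2,
                              in_gain_scale = rep(1, topology$n),
                              noise_sd = 0.3,
                              dt = 1e-3,
                              fs = 20,
                              duration = 30,
                              amplitude = rep(1, topology$n),
                              obs_noise_sd = 0.05,
                              init_phase = NULL,
                              seed = 1L) {
  stopifnot(inherits(topology, "topology"))
  n <- topology$n
  if (dt <= 0 || duration <= 0 || fs <= 0)
    stop("'dt', 'fs' and 'duration' must be positive")
  if (is.null(omega)) {
    omega <- local({
      set.seed(seed)
      2 * pi * stats::runif(n, omega_range[1], omega_range[2])
    })
  }
  if (length(omega) != n || any(!is.finite(omega)))
    stop("'omega' must hold one finite frequency per player")
  if (length(in_gain_scale) != n || any(in_gain_scale < 0 | in_gain_scale > 1))
    stop("'in_gain_scale' must lie in [0, 1], one value per player")
  if (any(amplitude <= 0)) stop("amplitudes must be positive")
  structure(list(topology = topology, omega = omega,
                 coupling_gain = coupling_gain,
                 in_gain_scale = in_gain_scale, noise_sd = noise_sd,
                 dt = dt, fs = fs, duration = duration,
                 amplitude = amplitude, obs_noise_sd = obs_noise_sd,
                 init_phase = init_phase, seed = as.integer(seed),
                 ground_truth = list(pattern = "NONE",
                                     leader_indices = integer(0),
                                     phase_extreme_indices = integer(0))),
            class = "oscillator_config")
}

#' Plant a leadership pattern in an oscillator configuration
#'
#' Realizes one of the three leadership scenarios in the generator by making
#' selected agents stubborn (attenuated incoming coupling): \code{"P1"} makes
#' the fastest oscillator (largest natural frequency) stubborn, so the phase
#' leader is also the influence leader ("the fastest leads"); \code{"P2"} the
#' slowest ("the slowest leads"); \code{"P3"} both extremes (shared
#' leadership); \code{"NONE"} leaves the configuration unchanged.
#'
#' For shared leadership (\code{"P3"}) the two stubborn agents' frequency
#' deviations are symmetrized about the group mean (both set to plus/minus
#' the larger deviation), so the planted leadership is balanced: two equally
#' detuned, equally stubborn agents on opposite sides of the group tempo.
#'
#' The default stubbornness \code{epsilon = 0.1} keeps a planted leader
#' quasi-phase-locked to the group: its maximum incoming pull
#' (epsilon * k * (N-1), about 1.2 rad/s at the defaults) stays above the
#' maximum natural detuning (about 0.63 rad/s), while its sensitivity to the
#' others remains 10 times below a regular player's. A fully slipping leader
#' would express little of its influence in the group's phase dynamics.
#'
#' @param pattern One of \code{"P1"}, \code{"P2"}, \code{"P3"}, \code{"NONE"}.
#' @param base An \code{\link{oscillator_config}} with homogeneous
#'   \code{in_gain_scale = 1}.
#' @param epsilon Incoming-coupling multiplier given to stubborn agents
#'   (much below 1).
#' @return A modified \code{oscillator_config} whose \code{ground_truth}
#'   records the planted pattern and leader indices.
#' @export
plant_pattern <- function(pattern = c("P1", "P2", "P3", "NONE"), base,
                          epsilon = 0.1) {
  pattern <- match.arg(pattern)
  stopifnot(inherits(base, "oscillator_config"))
  if (any(base$in_gain_scale != 1))
    stop("'base' must have homogeneous in_gain_scale = 1")
  fast <- which.max(base$omega)
  slow <- which.min(base$omega)
  cfg <- base
  leaders <- switch(pattern,
                    P1 = fast, P2 = slow, P3 = c(fast, slow),
                    NONE = integer(0))
  cfg$in_gain_scale[leaders] <- epsilon
  if (pattern == "P3") {
    ctr <- mean(base$omega)
    dev <- max(abs(base$omega[c(fast, slow)] - ctr))
    cfg$omega[fast] <- ctr + dev
    cfg$omega[slow] <- ctr - dev
  }
  cfg$ground_truth <- list(pattern = pattern,
                           leader_indices = as.integer(leaders),
                           phase_extreme_indices = c(fast = fast, slow = slow))
  cfg
}

#' Leaderless detuned variant of a configuration
#'
#' Builds the comparison condition for coordination analyses: a group with no
#' stubborn agent, more heterogeneous natural tempos (frequency deviations
#' scaled by \code{detune}) and weaker mutual coupling
#' (\code{coupling_scale}), emulating trials in which no leadership pattern
#' emerges and coordination is poorer.
#'
#' @param base An \code{\link{oscillator_config}}.
#' @param detune Multiplier on each player's deviation from the group mean
#'   frequency.
#' @param coupling_scale Multiplier on the coupling gain.
#' @return A leaderless \code{oscillator_config}.
#' @export
detune_config <- function(base, detune = 3, coupling_scale = 0.25) {
  stopifnot(inherits(base, "oscillator_config"))
  cfg <- base
  cfg$in_gain_scale <- rep(1, base$topology$n)
  om <- base$omega
  cfg$omega <- mean(om) + detune * (om - mean(om))
  cfg$coupling_gain <- base$coupling_gain * coupling_scale
  cfg$ground_truth <- list(pattern = "NONE", leader_indices = integer(0),
                           phase_extreme_indices = integer(0))
  cfg
}

#' Simulate the coupled phase-oscillator network
#'
#' Integrates the stochastic Kuramoto dynamics by Euler--Maruyama at the
#' internal step \code{config$dt} and decimates the unwrapped phases to the
#' trial sampling rate \code{config$fs}. Fully reproducible for a fixed
#' config (seeded).
#'
#' @param config An \code{\link{oscillator_config}}.
#' @return A list with \code{phases} (a \code{\link{phase_matrix}} of
#'   unwrapped phases, instants in rows, players in columns) and
#'   \code{ground_truth}.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "oscillator_config"))
  n <- config$topology$n
  a <- config$topology$adjacency
  dt <- config$dt
  n_steps <- round(config$duration / dt)
  keep_every <- max(1L, round(1 / (config$fs * dt)))
  ks <- config$coupling_gain * config$in_gain_scale # per-player gain s_i * k
  omega <- config$omega

  set.seed(config$seed + 1L)
  theta <- if (is.null(config$init_phase)) stats::runif(n, 0, 2 * pi)
           else rep_len(config$init_phase, n)
  noise <- if (config$noise_sd > 0)
    matrix(stats::rnorm(n_steps * n, sd = config$noise_sd * sqrt(dt)),
           n_steps, n)
  else NULL

  n_keep <- floor(n_steps / keep_every) + 1L
  out <- matrix(NA_real_, n_keep, n)
  out[1L, ] <- theta
  row <- 1L
  for (s in seq_len(n_steps)) {
    # sin(theta_j - theta_i) summed over observed neighbours j of player i:
    # with M[i, j] = theta_i - theta_j this is -rowSums(a * sin(M))
    drift <- omega - ks * rowSums(a * sin(outer(theta, theta, "-")))
    theta <- theta + drift * dt
    if (!is.null(noise)) theta <- theta + noise[s, ]
    if (s %% keep_every == 0L) {
      row <- row + 1L
      out[row, ] <- theta
    }
  }
  if (anyNA(out) || any(!is.finite(out)))
    stop("integration diverged: non-finite phases (check parameters)")
  phases <- phase_matrix(out, fs = config$fs,
                         source = sprintf("simulate_network seed=%d",
                                          config$seed))
  list(phases = phases, ground_truth = config$ground_truth)
}

#' Observe noisy positions from oscillator phases
#'
#' Applies the observation model \eqn{x_i(t_k) = A_i \sin\theta_i(t_k) +
#' \varepsilon_{ik}}, emulating the measured pendulum or finger displacement.
#'
#' @param phases A \code{\link{phase_matrix}}.
#' @param amplitude Positive amplitude, one per player (recycled if scalar).
#' @param obs_noise_sd Standard deviation of additive Gaussian observation
#'   noise.
#' @param seed RNG seed for the observation noise.
#' @param experiment Experiment tag stored on the recording (controls the
#'   preprocessing chain later applied).
#' @return A \code{\link{trial_recording}} of the same shape as the phases.
#' @export
positions_from_phases <- function(phases, amplitude = 1, obs_noise_sd = 0,
                                  seed = 1L, experiment = "synthetic") {
  stopifnot(inherits(phases, "phase_matrix"))
  n <- ncol(phases$theta)
  amplitude <- rep_len(amplitude, n)
  if (any(amplitude <= 0)) stop("amplitudes must be positive")
  x <- sweep(sin(phases$theta), 2L, amplitude, "*")
  if (obs_noise_sd > 0) {
    set.seed(seed)
    x <- x + matrix(stats::rnorm(length(x), sd = obs_noise_sd),
                    nrow(x), ncol(x))
  }
  trial_recording(x, fs = phases$fs, experiment = experiment)
}

#' Simulate a complete synthetic trial
#'
#' Convenience wrapper running \code{\link{simulate_network}} and
#' \code{\link{positions_from_phases}} for one configuration; the returned
#' recording carries the planted ground truth and topology label.
#'
#' @param config An \code{\link{oscillator_config}}.
#' @return A \code{\link{trial_recording}} with attributes \code{ground_truth}
#'   and the latent \code{phases}.
#' @export
simulate_trial <- function(config) {
  sim <- simulate_network(config)
  rec <- positions_from_phases(sim$phases, amplitude = config$amplitude,
                               obs_noise_sd = config$obs_noise_sd,
                               seed = config$seed + 2L)
  rec$topology <- config$topology$kind
  rec$seed <- config$seed
  rec$ground_truth <- sim$ground_truth
  rec
}
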