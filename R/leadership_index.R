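#' Pairwise phase differences
#'
#' Computes the tensor \eqn{\phi_{ij}(t_k) = \theta_i(t_k) - \theta_j(t_k)}
#' for every ordered pair of players and every instant. With
#' \code{convention = "wrapped_pi"} each difference is mapped to the interval
#' (-pi, pi]; the default keeps the raw (unwrapped) differences so that
#' "ahead in phase" is globally comparable.
#'
#' @param theta A \code{\link{phase_matrix}} or a numeric matrix of unwrapped
#'   phases (instants in rows, players in columns).
#' @param convention \code{"unwrapped"} or \code{"wrapped_pi"}.
#' @return A numeric array of dimension \code{N x N x N_instants} with
#'   attribute \code{convention}; antisymmetric with zero diagonal.
#' @export
pairwise_phase_diff <- function(theta, convention = c("unwrapped",
                                                      "wrapped_pi")) {
  convention <- match.arg(convention)
  th <- if (inherits(theta, "phase_matrix")) theta$theta else as.matrix(theta)
  if (any(!is.finite(th))) stop("phases must be finite")
  n <- ncol(th)
  nt <- nrow(th)
  phi <- array(apply(th, 1L, function(r) outer(r, r, "-")),
               dim = c(n, n, nt))
  if (convention == "wrapped_pi")
    phi <- phi - 2 * pi * ceiling((phi - pi) / (2 * pi))
  attr(phi, "convention") <- convention
  phi
}

#' Instantaneous phase leadership index
#'
#' For each instant, player i's index is one plus the number of other players
#' whose phase is at or ahead of player i's
#' (\eqn{H_i = |\{j \neq i : \theta_j \ge \theta_i\}| + 1}).
#' \code{H = 1} marks the instantaneous phase leader and \code{H = N} the
#' laggard; phase-tied players count as ahead of each other, so an all-tied
#' instant yields \code{H = N} for everyone.
#'
#' With \code{convention = "unwrapped"} (the default) phases are compared as
#' given, so being a full cycle ahead counts as ahead. With
#' \code{"wrapped_pi"} each pairwise difference is first mapped to
#' (-pi, pi], the natural choice for near-synchronous groups where a player
#' that slips one full cycle should not become a permanent laggard; under
#' this convention the indices need not form a permutation when the group is
#' widely dispersed.
#'
#' @param theta Numeric vector of N phases at one instant, a numeric matrix
#'   (instants in rows), or a \code{\link{phase_matrix}}.
#' @param convention Pairwise-difference convention, \code{"unwrapped"} or
#'   \code{"wrapped_pi"}.
#' @return An integer vector (or matrix, matching the input shape) of
#'   indices in \code{1..N}.
#' @export
leadership_index <- function(theta, convention = c("unwrapped",
                                                   "wrapped_pi")) {
  convention <- match.arg(convention)
  if (inherits(theta, "phase_matrix")) theta <- theta$theta
  rank1 <- function(r) {
    n <- length(r)
    if (convention == "unwrapped")
      return(as.integer(n - rank(r, ties.method = "min") + 1L))
    phi <- outer(r, r, "-")
    phi <- phi - 2 * pi * ceiling((phi - pi) / (2 * pi))
    vapply(seq_len(n), function(i) 1L + sum(phi[i, -i] <= 0), integer(1))
  }
  if (is.matrix(theta)) {
    if (ncol(theta) < 2L) stop("need at least 2 players")
    t(apply(theta, 1L, rank1))
  } else {
    if (length(theta) < 2L) stop("need at least 2 players")
    rank1(theta)
  }
}

#' Mean phase leadership index
#'
#' Time average of the instantaneous leadership index over the retained
#' (end-trimmed) instants; values lie in [1, N], with small values marking
#' players who tend to lead in phase.
#'
#' @param H Integer matrix of instantaneous indices (instants in rows), as
#'   returned by \code{\link{leadership_index}}.
#' @return Numeric vector of per-player means \eqn{\bar{H}_i}.
#' @export
mean_leadership_index <- function(H) {
  if (!is.matrix(H) || nrow(H) == 0L) stop("'H' must be a nonempty matrix")
  colMeans(H)
}
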