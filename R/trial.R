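#' Trial recording container
#'
#' Holds one trial's multivariate position time series: instants in rows,
#' players in columns, on a uniform time grid.
#'
#' @param positions Numeric matrix, \code{N_instants x N_players}; all finite.
#' @param fs Sampling rate (Hz).
#' @param player_ids Column labels; defaults to \code{p1..pN}.
#' @param topology Optional topology label.
#' @param experiment One of \code{"pendula"}, \code{"chronos"},
#'   \code{"synthetic"}; selects the preprocessing chain.
#' @return An object of class \code{"trial_recording"}.
#' @export
trial_recording <- function(positions, fs, player_ids = NULL,
                            topology = NA_character_,
                            experiment = c("synthetic", "pendula", "chronos")) {
  experiment <- match.arg(experiment)
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || any(!is.finite(positions)))
    stop("'positions' must be a finite numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive sampling rate in Hz")
  if (is.null(player_ids)) player_ids <- paste0("p", seq_len(ncol(positions)))
  colnames(positions) <- player_ids
  structure(list(positions = positions, fs = fs, dt = 1 / fs,
                 duration = (nrow(positions) - 1L) / fs,
                 player_ids = player_ids, topology = topology,
                 experiment = experiment),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording: %d players, %d instants @ %g Hz (%.1f s), %s%s>\n",
    ncol(x$positions), nrow(x$positions), x$fs, x$duration, x$experiment,
    if (is.na(x$topology)) "" else paste0(", topology=", x$topology)))
  invisible(x)
}

#' Unwrapped phase container
#'
#' @param theta Numeric matrix of unwrapped phases (rad), instants in rows,
#'   players in columns.
#' @param fs Sampling rate (Hz).
#' @param source Free-text provenance note (e.g. the preprocessing chain).
#' @return An object of class \code{"phase_matrix"}.
#' @export
phase_matrix <- function(theta, fs, source = "unspecified") {
  theta <- as.matrix(theta)
  if (any(!is.finite(theta))) stop("phases must be finite")
  structure(list(theta = theta, fs = fs, source = source),
            class = "phase_matrix")
}

#' @export
print.phase_matrix <- function(x, ...) {
  cat(sprintf("<phase_matrix: %d players, %d instants @ %g Hz [%s]>\n",
              ncol(x$theta), nrow(x$theta), x$fs, x$source))
  invisible(x)
}

#' Write a trial to wide CSV with a JSON sidecar
#'
#' The CSV has a time column \code{t} (seconds, 6 decimals) followed by one
#' position column per player (\code{p1..pN}). A sidecar
#' \code{<stem>.json} stores \code{n_players}, \code{fs_hz}, \code{topology},
#' \code{experiment}, and, for synthetic trials, \code{seed} and
#' \code{ground_truth}.
#'
#' @param x A \code{\link{trial_recording}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trial <- function(x, path) {
  stopifnot(inherits(x, "trial_recording"))
  tt <- (seq_len(nrow(x$positions)) - 1L) / x$fs
  df <- data.frame(t = sprintf("%.6f", tt))
  for (j in seq_along(x$player_ids))
    df[[x$player_ids[j]]] <- x$positions[, j]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(n_players = ncol(x$positions), fs_hz = x$fs,
               topology = x$topology, experiment = x$experiment)
  if (!is.null(x$seed)) side$seed <- x$seed
  if (!is.null(x$ground_truth)) side$ground_truth <- x$ground_truth
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read a trial from wide CSV (+ JSON sidecar)
#'
#' Expects the format written by \code{\link{write_trial}}. If the sidecar is
#' missing, the sampling rate is inferred from the median time step and a
#' warning is issued. Non-finite cells and non-monotone time stamps are
#' rejected with the offending row named.
#'
#' @param path CSV path.
#' @return A \code{\link{trial_recording}}.
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path)
  if (!"t" %in% names(df)) stop("missing time column 't' in ", path)
  tt <- df$t
  if (any(diff(tt) <= 0))
    stop("non-monotone time column at row ", which(diff(tt) <= 0)[1] + 1L)
  pos <- as.matrix(df[setdiff(names(df), "t")])
  bad <- which(!is.finite(pos), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite value at row %d, column '%s'",
                 bad[1, 1], colnames(pos)[bad[1, 2]]))
  sc <- sidecar_path(path)
  topology <- NA_character_; experiment <- "synthetic"
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    fs <- side$fs_hz
    if (!is.null(side$topology) && !is.na(side$topology))
      topology <- side$topology
    if (!is.null(side$experiment)) experiment <- side$experiment
  } else {
    fs <- 1 / stats::median(diff(tt))
    warning("sidecar not found; inferred fs = ", signif(fs, 6), " Hz")
  }
  rec <- trial_recording(pos, fs = fs, player_ids = colnames(pos),
                         topology = topology, experiment = experiment)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(side$seed)) rec$seed <- side$seed
    if (!is.null(side$ground_truth)) rec$ground_truth <- side$ground_truth
  }
  rec
}
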