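#' Visual-coupling topology of a group
#'
#' Builds the directed adjacency matrix describing who can observe whom in a
#' group of \code{n} players. Entry \code{a[i, j] = 1} means player \code{i}
#' observes player \code{j}. Four structures are supported: \code{complete}
#' (everyone sees everyone), \code{path} (a chain; the two endpoints see one
#' neighbour, interior players two), \code{ring} (a cycle; everyone sees two
#' neighbours) and \code{star} (a hub sees all leaves and every leaf sees only
#' the hub). By convention the star hub is player 1.
#'
#' @param kind One of \code{"complete"}, \code{"path"}, \code{"ring"},
#'   \code{"star"}.
#' @param n Number of players (at least 3).
#' @return An object of class \code{"topology"}: a list with \code{kind},
#'   \code{n} and the \code{n x n} binary \code{adjacency} matrix
#'   (zero diagonal).
#' @examples
#' top <- make_topology("star", 4)
#' top$adjacency
#' @export
make_topology <- function(kind = c("complete", "path", "ring", "star"), n) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || length(n) != 1L || n < 3 || n != round(n))
    stop("'n' must be a single integer >= 3")
  n <- as.integer(n)
  a <- matrix(0L, n, n)
  idx <- seq_len(n)
  if (kind == "complete") {
    a[] <- 1L
  } else if (kind == "path") {
    a[cbind(idx[-n], idx[-1])] <- 1L
    a[cbind(idx[-1], idx[-n])] <- 1L
  } else if (kind == "ring") {
    nxt <- c(idx[-1], 1L)
    a[cbind(idx, nxt)] <- 1L
    a[cbind(nxt, idx)] <- 1L
  } else { # star, hub = player 1
    a[1L, -1L] <- 1L
    a[-1L, 1L] <- 1L
  }
  diag(a) <- 0L
  structure(list(kind = kind, n = n, adjacency = a), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology: %s graph, %d players, %d directed edges>\n",
              x$kind, x$n, sum(x$adjacency)))
  invisible(x)
}
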