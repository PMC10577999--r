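#' Extract boundary residence events from a trajectory
#'
#' A residence event starts at a time `t1` when `|x(t)|` achieves a local
#' maximum within `contact_margin` cm of the `|x| = L/2` wall (an ant whose
#' center of mass comes within half a body length of the edge has contacted
#' it), and ends at the earliest later time `t2` at which the ant has moved
#' beyond the boundary strip, `|x(t2)| < L/2 - strip_width`. The residence
#' time is `t_b = t2 - t1`. Only the x coordinate is used, which avoids
#' special-casing arena corners; `+x` and `-x` wall events are pooled by
#' symmetry.
#'
#' Discrete local maxima are runs of equal `|x|` that exceed both
#' neighbouring values, collapsed to their first index (stop-mode
#' trajectories produce exact plateaus on the wall). Within one strip
#' sojourn only the first qualifying maximum opens an event; later maxima
#' before the exit are absorbed. An event whose exit has not occurred by the
#' end of the series is censored and dropped (the count is reported as an
#' attribute).
#'
#' @param x An `ant_trajectory`, `ant_trajectory_1d`, or `ant_ensemble`
#'   (events are pooled over trials).
#' @param contact_margin Contact distance from the wall, cm.
#' @param strip_width Width of the boundary strip, cm.
#' @return A data.frame of class `residence_events` with columns `ant`, `t1`,
#'   `t2`, `t_b` (s) , `vx_at_t1` (cm/s, motion towards the wall positive —
#'   events always have `vx_at_t1 <= 0`) and `wall` (`"+x"`/`"-x"`);
#'   attributes `n_censored` and `dt`.
#' @export
find_events <- function(x, contact_margin = 0.5, strip_width = 3) {
  if (inherits(x, c("ant_ensemble", "ant_ensemble_1d"))) {
    parts <- lapply(seq_along(x$trajectories), function(j) {
      ev <- find_events(x$trajectories[[j]], contact_margin, strip_width)
      if (nrow(ev)) ev$ant <- j
      ev
    })
    out <- do.call(rbind, parts)
    attr(out, "n_censored") <- sum(vapply(parts, attr, numeric(1), "n_censored"))
    attr(out, "dt") <- x$trajectories[[1]]$dt
    class(out) <- c("residence_events", "data.frame")
    return(out)
  }
  xs <- if (inherits(x, "ant_trajectory_1d")) as.numeric(x$positions)
        else x$positions[, 1]
  L <- if (inherits(x, "ant_trajectory_1d")) x$L else x$arena$L
  dt <- x$dt
  a <- abs(xs)
  contact <- L / 2 - contact_margin
  exit <- L / 2 - strip_width
  r <- rle(a)
  k <- length(r$values)
  starts <- cumsum(c(1L, r$lengths[-k]))
  is_max <- rep(FALSE, k)
  if (k >= 3L)
    is_max[2:(k - 1L)] <- r$values[2:(k - 1L)] > r$values[1:(k - 2L)] &
      r$values[2:(k - 1L)] > r$values[3:k]
  cand <- starts[is_max & r$values >= contact]
  events <- list()
  n_censored <- 0L
  pos_exit <- which(a < exit)
  last_exit <- 0L  # end of the current sojourn handled so far
  for (i1 in cand) {
    if (i1 <= last_exit) next  # absorbed into an open event
    j <- pos_exit[pos_exit > i1]
    if (!length(j)) {
      n_censored <- n_censored + 1L
      break
    }
    i2 <- j[1L]
    events[[length(events) + 1L]] <- data.frame(
      ant = 1L,
      t1 = (i1 - 1L) * dt, t2 = (i2 - 1L) * dt,
      t_b = (i2 - i1) * dt,
      vx_at_t1 = sign(xs[i1]) * (xs[i1 + 1L] - xs[i1]) / dt,
      wall = if (xs[i1] > 0) "+x" else "-x")
    last_exit <- i2
  }
  out <- if (length(events)) do.call(rbind, events)
         else data.frame(ant = integer(0), t1 = numeric(0), t2 = numeric(0),
                         t_b = numeric(0), vx_at_t1 = numeric(0),
                         wall = character(0))
  attr(out, "n_censored") <- n_censored
  attr(out, "dt") <- dt
  class(out) <- c("residence_events", "data.frame")
  out
}

#' Residence-time and contact-velocity distributions
#'
#' Normalized histograms of the boundary residence time `t_b` and of the
#' wall-normal velocity at contact. The same fixed binning is applied to any
#' event set, so model and observed trajectories processed with the same
#' procedure are directly comparable.
#'
#' @param events A `residence_events` table with at least one event.
#' @param bin_width Histogram bin width (s for times, cm/s for velocities).
#' @return A data.frame with bin midpoints (`mid`) and `density`; the
#'   histogram integrates to 1.
#' @export
residence_distribution <- function(events, bin_width = 0.2) {
  stopifnot(inherits(events, "residence_events"))
  if (!nrow(events)) stop("no residence events", call. = FALSE)
  hist1d(events$t_b, bin_width, origin = 0)
}

#' @rdname residence_distribution
#' @export
contact_velocity_distribution <- function(events, bin_width = 0.5) {
  stopifnot(inherits(events, "residence_events"))
  if (!nrow(events)) stop("no residence events", call. = FALSE)
  v <- events$vx_at_t1
  hist1d(v, bin_width, origin = floor(min(v) / bin_width) * bin_width)
}

hist1d <- function(x, bin_width, origin) {
  hi <- ceiling((max(x) - origin) / bin_width + 1e-12) * bin_width + origin
  edges <- seq(origin, max(hi, origin + bin_width), by = bin_width)
  cnt <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                       length(edges) - 1L),
                  nbins = length(edges) - 1L)
  data.frame(mid = (edges[-1] + edges[-length(edges)]) / 2,
             density = cnt / (sum(cnt) * bin_width))
}
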