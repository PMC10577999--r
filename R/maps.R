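#' Occupancy density map of an ensemble
#'
#' Two-dimensional histogram of all recorded positions, normalized so that
#' the areal density integrates to 1 over the arena.
#'
#' @param ensemble An `ant_ensemble` in a stop-mode arena.
#' @param bin Spatial bin width, cm.
#' @return An object of class `density_field`: list with `x_edges`,
#'   `y_edges` and the density matrix `values` (cm^-2, x indexing rows).
#' @export
density_map <- function(ensemble, bin = 1) {
  stopifnot(inherits(ensemble, "ant_ensemble"))
  half <- ensemble$arena$L / 2
  edges <- seq(-half, half, by = bin)
  pos <- do.call(rbind, lapply(ensemble$trajectories, `[[`, "positions"))
  hist2 <- bin2d(pos[, 1], pos[, 2], edges, edges)
  structure(list(x_edges = edges, y_edges = edges,
                 values = hist2 / (sum(hist2) * bin * bin)),
            class = "density_field")
}

#' Velocity distribution map of an ensemble
#'
#' Two-dimensional histogram of finite-difference velocities, optionally
#' restricted to samples whose position at the start of the interval lies in
#' the arena interior or in the boundary strip (the `strip_width` cm rule).
#' Normalized to integrate to 1.
#'
#' @param ensemble An `ant_ensemble`.
#' @param region `"all"`, `"interior"` or `"boundary_strip"`.
#' @param bin Velocity bin width, cm/s.
#' @param vmax Half-range of the map (cm/s); defaults to the smallest
#'   multiple of `bin` covering the samples.
#' @param strip_width Width of the boundary strip, cm.
#' @return An object of class `velocity_field`: list with `x_edges`,
#'   `y_edges` (cm/s) and density matrix `values` ((cm/s)^-2).
#' @export
velocity_map <- function(ensemble, region = c("all", "interior", "boundary_strip"),
                         bin = 0.5, vmax = NULL, strip_width = 3) {
  stopifnot(inherits(ensemble, "ant_ensemble"))
  region <- match.arg(region)
  half <- ensemble$arena$L / 2
  vs <- lapply(ensemble$trajectories, function(tr) {
    vel <- diff(tr$positions) / tr$dt
    p <- tr$positions[seq_len(nrow(vel)), , drop = FALSE]
    interior <- pmax(abs(p[, 1]), abs(p[, 2])) < half - strip_width
    keep <- switch(region, all = rep(TRUE, nrow(vel)),
                   interior = interior, boundary_strip = !interior)
    vel[keep, , drop = FALSE]
  })
  v <- do.call(rbind, vs)
  if (is.null(vmax)) vmax <- ceiling(max(abs(v), 1e-9) / bin) * bin
  edges <- seq(-vmax, vmax, by = bin)
  v <- v[pmax(abs(v[, 1]), abs(v[, 2])) <= vmax, , drop = FALSE]
  hist2 <- bin2d(v[, 1], v[, 2], edges, edges)
  structure(list(x_edges = edges, y_edges = edges,
                 values = hist2 / (sum(hist2) * bin * bin)),
            class = "velocity_field")
}

# simple 2D bin counts; rows index x
bin2d <- function(x, y, x_edges, y_edges) {
  ix <- findInterval(x, x_edges, rightmost.closed = TRUE)
  iy <- findInterval(y, y_edges, rightmost.closed = TRUE)
  nx <- length(x_edges) - 1L
  ny <- length(y_edges) - 1L
  ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  counts <- tabulate((iy[ok] - 1L) * nx + ix[ok], nbins = nx * ny)
  matrix(counts, nrow = nx, ncol = ny)
}

#' One-dimensional marginal of a distribution field
#'
#' Integrates a [density_map()] or [velocity_map()] over one coordinate,
#' e.g. \eqn{n(x) = \int dy\, n(x, y)} or
#' \eqn{P(v_x) = \int dv_y\, P(v_x, v_y)}. The returned profile integrates
#' to 1.
#'
#' @param field A `density_field` or `velocity_field`.
#' @param axis Which coordinate to keep: `"x"` or `"y"`.
#' @return A data.frame with the bin centers (`pos`) and marginal `density`.
#' @export
marginal <- function(field, axis = c("x", "y")) {
  axis <- match.arg(axis)
  stopifnot(inherits(field, c("density_field", "velocity_field")))
  if (axis == "x") {
    width <- diff(field$y_edges)
    dens <- as.vector(field$values %*% width)
    mids <- (field$x_edges[-1] + field$x_edges[-length(field$x_edges)]) / 2
  } else {
    width <- diff(field$x_edges)
    dens <- as.vector(t(field$values) %*% width)
    mids <- (field$y_edges[-1] + field$y_edges[-length(field$y_edges)]) / 2
  }
  data.frame(pos = mids, density = dens)
}

#' Near-wall density exponent of the 1D model
#'
#' In the continuum limit the 1D stop-mode density diverges towards a wall as
#' \eqn{n \sim d^{-2/3}} for wall distance \eqn{d \ll \ell}. This fits a
#' log-log least-squares line to the binned density of wall distances over
#' `fit_range` (log-spaced bins; the wall-contact atom at `d = 0` lies below
#' the range and is excluded).
#'
#' @param x An `ant_ensemble_1d`, or a numeric vector of wall distances (cm).
#' @param ell Localization length \eqn{\ell} (cm), used for the default
#'   range.
#' @param fit_range Distance interval (cm) over which to fit.
#' @param n_bins Number of log-spaced bins.
#' @param burn_in Steps discarded from the start of each series before
#'   pooling (equilibration).
#' @return An object of class `wall_exponent`: list with `exponent`, `se`,
#'   `n` (samples in range) and the binned profile.
#' @export
near_wall_exponent <- function(x, ell, fit_range = c(ell / 50, ell / 2),
                               n_bins = 16L, burn_in = 0L) {
  if (inherits(x, "ant_ensemble_1d")) {
    d <- unlist(lapply(x$trajectories, function(tr) {
      p <- tr$positions
      if (burn_in > 0L) p <- p[-seq_len(min(burn_in, length(p)))]
      x$L / 2 - abs(p)
    }), use.names = FALSE)
  } else {
    d <- as.numeric(x)
  }
  stopifnot(fit_range[1] > 0, fit_range[2] > fit_range[1])
  sel <- d >= fit_range[1] & d < fit_range[2]
  if (sum(sel) < 100L)
    stop("insufficient near-wall samples: ", sum(sel), call. = FALSE)
  edges <- exp(seq(log(fit_range[1]), log(fit_range[2]),
                   length.out = n_bins + 1L))
  cnt <- tabulate(findInterval(d[sel], edges, rightmost.closed = TRUE),
                  nbins = n_bins)
  dens <- cnt / diff(edges)
  ctr <- sqrt(edges[-1] * edges[-length(edges)])
  ok <- cnt > 0
  if (sum(ok) < 5L)
    stop("insufficient occupied bins for the log-log fit", call. = FALSE)
  fit <- stats::lm(log(dens[ok]) ~ log(ctr[ok]))
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 se = sqrt(diag(stats::vcov(fit)))[[2]],
                 n = sum(sel),
                 profile = data.frame(d = ctr, density = dens)),
            class = "wall_exponent")
}

#' @export
print.wall_exponent <- function(x, ...) {
  cat(sprintf("Near-wall density exponent: %.3f +- %.3f (n = %d)\n",
              x$exponent, x$se, x$n))
  invisible(x)
}
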