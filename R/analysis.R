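#' Finite-difference velocities of a trajectory
#'
#' The measurement convention of the tracking pipeline:
#' `v(t) = (x[t + dt] - x[t]) / dt`, a forward difference, giving a series
#' one shorter than the positions. Applied identically to observed and
#' simulated trajectories.
#'
#' @param traj An `ant_trajectory` (or anything with a `positions` matrix and
#'   `dt`).
#' @return Numeric `n x 2` matrix of velocities (cm/s) with attribute `t`,
#'   the time stamps of the differenced intervals.
#' @export
velocities <- function(traj) {
  pos <- traj$positions
  if (nrow(pos) < 2L) stop("need at least 2 positions", call. = FALSE)
  v <- diff(pos) / traj$dt
  attr(v, "t") <- (seq_len(nrow(v)) - 1) * traj$dt
  v
}

#' Decompose velocity changes into transverse and longitudinal components
#'
#' For each time `t` with measured velocity `v(t)` and velocity change
#' `dv(t) = v(t + dt) - v(t)`, resolves `dv` in the frame of `v`:
#' \deqn{\Delta v = \Delta v_T\,\hat z\times\hat v + \Delta v_L\,\hat v,}
#' so that a positive `dv_T` is a left turn and `dv_L` is the change of
#' speed. Samples with speed below `speed_floor` are excluded (the frame
#' direction is ill-defined); their count is returned as attribute
#' `n_excluded`. Each sample is tagged `interior` or `boundary_strip` by the
#' position at time `t` relative to the strip rule (within `strip_width` cm
#' of a wall).
#'
#' @param x An `ant_trajectory` or `ant_ensemble`.
#' @param speed_floor Minimum speed (cm/s) for frame decomposition.
#' @param strip_width Width of the boundary strip (cm).
#' @return A data.frame with columns `ant`, `t`, `speed`, `dv_T`, `dv_L`,
#'   `region`; attributes `n_excluded` and `dt`.
#' @export
decompose_dv <- function(x, speed_floor = 0.1, strip_width = 3) {
  if (inherits(x, "ant_ensemble")) {
    parts <- lapply(seq_along(x$trajectories), function(j) {
      d <- decompose_dv(x$trajectories[[j]], speed_floor, strip_width)
      d$ant <- j
      d
    })
    out <- do.call(rbind, parts)
    attr(out, "n_excluded") <- sum(vapply(parts, attr, numeric(1), "n_excluded"))
    attr(out, "dt") <- x$trajectories[[1]]$dt
    return(out)
  }
  stopifnot(inherits(x, "ant_trajectory"))
  pos <- x$positions
  if (nrow(pos) < 3L) stop("need at least 3 positions", call. = FALSE)
  vel <- diff(pos) / x$dt
  dv <- diff(vel)
  n <- nrow(dv)
  v <- vel[seq_len(n), , drop = FALSE]
  sp <- sqrt(rowSums(v^2))
  keep <- sp >= speed_floor
  eL <- v[keep, , drop = FALSE] / sp[keep]
  dvk <- dv[keep, , drop = FALSE]
  p <- pos[seq_len(n), , drop = FALSE][keep, , drop = FALSE]
  half <- x$arena$L / 2
  interior <- pmax(abs(p[, 1]), abs(p[, 2])) < half - strip_width
  out <- data.frame(
    ant = 1L,
    t = ((seq_len(n) - 1) * x$dt)[keep],
    speed = sp[keep],
    dv_T = dvk[, 1] * (-eL[, 2]) + dvk[, 2] * eL[, 1],
    dv_L = dvk[, 1] * eL[, 1] + dvk[, 2] * eL[, 2],
    region = ifelse(interior, "interior", "boundary_strip"))
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "dt") <- x$dt
  out
}

#' Per-speed-bin Laplace fits of velocity changes
#'
#' Sub-divides interior velocity-change samples by the speed at which the
#' change occurred and fits the Laplace law to the chosen component in each
#' bin by maximum likelihood. Bins with fewer than `min_n` samples are
#' dropped (a small-bin sigma estimate carries too large a standard error to
#' be useful).
#'
#' @param samples Output of [decompose_dv()].
#' @param component `"T"` (transverse) or `"L"` (longitudinal).
#' @param bin_width Speed bin width, cm/s.
#' @param min_n Minimum bin occupancy.
#' @param region Which samples to use; the model is parameterized from
#'   `"interior"` data.
#' @param detrend Optional `force_fit` object; its fitted linear mean
#'   `intercept + slope * speed` is subtracted from each sample before
#'   fitting, isolating the random part of the longitudinal change.
#' @return A data.frame of class `laplace_fits` with columns `bin_low`,
#'   `bin_high`, `bin_center`, `n`, `q_bar`, `sigma`.
#' @export
bin_and_fit <- function(samples, component = c("T", "L"), bin_width = 1,
                        min_n = 200L, region = "interior", detrend = NULL) {
  component <- match.arg(component)
  if (!is.null(region)) samples <- samples[samples$region == region, ]
  q <- if (component == "T") samples$dv_T else samples$dv_L
  if (!is.null(detrend)) {
    stopifnot(inherits(detrend, "force_fit"))
    q <- q - (detrend$intercept + detrend$slope * samples$speed)
  }
  edges <- seq(0, ceiling(max(samples$speed) / bin_width) * bin_width,
               by = bin_width)
  idx <- findInterval(samples$speed, edges, rightmost.closed = TRUE)
  rows <- lapply(seq_len(length(edges) - 1L), function(i) {
    qi <- q[idx == i]
    if (length(qi) < min_n) return(NULL)
    f <- fit_laplace(qi)
    data.frame(bin_low = edges[i], bin_high = edges[i + 1L],
               bin_center = (edges[i] + edges[i + 1L]) / 2,
               n = f$n, q_bar = f$q_bar, sigma = f$sigma)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop("insufficient data: no speed bin reaches the minimum occupancy of ",
         min_n, call. = FALSE)
  out <- do.call(rbind, rows)
  class(out) <- c("laplace_fits", "data.frame")
  attr(out, "component") <- component
  attr(out, "bin_width") <- bin_width
  out
}

#' Recover drag and drive constants from the longitudinal mean
#'
#' The mean velocity change of the model at speed `v` is deterministic,
#' \eqn{\langle\Delta v\rangle = \Delta t\,F(v)}, so the longitudinal bin
#' means fall on the line \eqn{\bar q(v) = \Delta t (v_0 - v)/\tau_D}.
#' A weighted least-squares line through the bin means inside the fit window
#' (weights = bin occupancy) then gives
#' \eqn{\hat\tau_D = -\Delta t/\mathrm{slope}} and
#' \eqn{\hat v_0 = -\mathrm{intercept}/\mathrm{slope}}.
#'
#' @param fits_L A `laplace_fits` table for the longitudinal component.
#' @param dt Time step used when the samples were recorded, s.
#' @param window Speed interval (cm/s) over which the linear law is fitted;
#'   the default covers the range where most of the data falls and the mean
#'   is linear.
#' @return An object of class `force_fit`: list with `tau_D_hat`, `v0_hat`,
#'   `slope`, `intercept`, their standard errors, `window` and `n_bins`.
#' @export
fit_force_params <- function(fits_L, dt, window = c(3, 10)) {
  sel <- fits_L$bin_center >= window[1] & fits_L$bin_center <= window[2]
  if (sum(sel) < 3L)
    stop("need at least 3 speed bins inside the fit window", call. = FALSE)
  d <- fits_L[sel, ]
  fit <- stats::lm(q_bar ~ bin_center, data = d, weights = d$n)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  slope <- unname(co[2])
  intercept <- unname(co[1])
  if (slope >= 0)
    stop("no drag signal: fitted slope of the longitudinal mean is non-negative",
         call. = FALSE)
  structure(list(tau_D_hat = -dt / slope, v0_hat = -intercept / slope,
                 slope = slope, intercept = intercept,
                 slope_se = unname(se[2]), intercept_se = unname(se[1]),
                 window = window, n_bins = nrow(d)),
            class = "force_fit")
}

#' @export
print.force_fit <- function(x, ...) {
  cat(sprintf(
    "Force fit over [%g, %g] cm/s (%d bins): tau_D = %.4f s, v0 = %.4f cm/s\n",
    x$window[1], x$window[2], x$n_bins, x$tau_D_hat, x$v0_hat))
  invisible(x)
}

#' Pooled lag autocorrelation of velocity-change components
#'
#' Pearson correlation of a velocity-change component with itself `lag` steps
#' later, computed within each trajectory (never across trial boundaries) and
#' pooled with sample-size weights. Lag 3 is the closest spacing at which the
#' two finite differences share no position measurements. By default only
#' interior samples enter (the impulse frame is clean there; near walls the
#' measured velocity changes are shaped by the stop protocol). Samples
#' excluded by the speed floor or region rule leave gaps; only complete pairs
#' enter.
#'
#' @param x An `ant_trajectory`, `ant_ensemble`, or a plain numeric series.
#' @param lag Lag in time steps.
#' @param component `"T"` or `"L"` (ignored for numeric input).
#' @param speed_floor Passed to [decompose_dv()].
#' @param region `"interior"` (default) or `"all"`; ignored for numeric
#'   input.
#' @param strip_width Width of the boundary strip, cm.
#' @return Pooled correlation coefficient with attribute `n`, the number of
#'   pairs used.
#' @export
lag_correlation <- function(x, lag = 3L, component = c("T", "L"),
                            speed_floor = 0.1,
                            region = c("interior", "all"), strip_width = 3) {
  component <- match.arg(component)
  region <- match.arg(region)
  series <- if (is.numeric(x)) {
    list(x)
  } else {
    trajs <- if (inherits(x, "ant_ensemble")) x$trajectories else list(x)
    lapply(trajs, function(tr) {
      pos <- tr$positions
      vel <- diff(pos) / tr$dt
      dv <- diff(vel)
      v <- vel[seq_len(nrow(dv)), , drop = FALSE]
      sp <- sqrt(rowSums(v^2))
      eL <- v / ifelse(sp > 0, sp, 1)
      s <- if (component == "T") dv[, 1] * (-eL[, 2]) + dv[, 2] * eL[, 1]
           else dv[, 1] * eL[, 1] + dv[, 2] * eL[, 2]
      s[sp < speed_floor] <- NA_real_
      if (region == "interior") {
        p <- tr$positions[seq_len(nrow(dv)), , drop = FALSE]
        half <- tr$arena$L / 2
        s[pmax(abs(p[, 1]), abs(p[, 2])) >= half - strip_width] <- NA_real_
      }
      s
    })
  }
  rs <- ns <- numeric(0)
  for (s in series) {
    m <- length(s)
    if (m <= lag + 2L) next
    a <- s[seq_len(m - lag)]
    b <- s[seq_len(m - lag) + lag]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L) next
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      stop("degenerate series: zero variance", call. = FALSE)
    rs <- c(rs, stats::cor(a[ok], b[ok]))
    ns <- c(ns, sum(ok))
  }
  if (!length(rs)) stop("series too short for lag ", lag, call. = FALSE)
  structure(sum(rs * ns) / sum(ns), n = sum(ns))
}
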