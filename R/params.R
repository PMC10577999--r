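#' Model parameters for the arena Langevin model
#'
#' Bundles the five primitive constants of the movement model. Units are
#' centimetres and seconds throughout the package; dimensionless quantities
#' are always separate fields, never unit-carrying ones.
#'
#' The defaults are the values fitted to tracked weaver-ant trajectories in
#' the interior of a 30 cm arena: impulse standard deviations
#' \eqn{\sigma_T \approx 1.00} cm/s (transverse) and
#' \eqn{\sigma_L \approx 1.25} cm/s (longitudinal), drag time
#' \eqn{\tau_D = 0.55} s, drive speed \eqn{v_0 = 6.3} cm/s, and frame
#' interval \eqn{\Delta t = 1/15} s.
#'
#' @param sigma_T Standard deviation of the transverse (turning) impulse, cm/s.
#' @param sigma_L Standard deviation of the longitudinal (speed) impulse, cm/s.
#' @param tau_D Drag relaxation time, s.
#' @param v0 Drive speed at which drag and drive balance, cm/s.
#' @param dt Time step of the discrete update, s. Must be smaller than
#'   `tau_D` for the update to be a stable Euler step.
#' @return An object of class `ant_params`.
#' @examples
#' p <- model_params()
#' derive_scales(p)
#' @export
model_params <- function(sigma_T = 1.00, sigma_L = 1.25, tau_D = 0.55,
                         v0 = 6.3, dt = 1 / 15) {
  p <- list(sigma_T = sigma_T, sigma_L = sigma_L, tau_D = tau_D,
            v0 = v0, dt = dt)
  for (nm in names(p)) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("invalid parameter '", nm, "': must be a finite number",
           call. = FALSE)
  }
  # sigma_T = 0 or sigma_L = 0 is allowed as the noise-free limit used for
  # deterministic checks; the time scales must be strictly positive.
  if (sigma_T < 0) stop("invalid parameter 'sigma_T': must be >= 0", call. = FALSE)
  if (sigma_L < 0) stop("invalid parameter 'sigma_L': must be >= 0", call. = FALSE)
  if (tau_D <= 0) stop("invalid parameter 'tau_D': must be > 0", call. = FALSE)
  if (v0 <= 0) stop("invalid parameter 'v0': must be > 0", call. = FALSE)
  if (dt <= 0) stop("invalid parameter 'dt': must be > 0", call. = FALSE)
  if (dt >= tau_D)
    stop("invalid parameter 'dt': must be smaller than tau_D", call. = FALSE)
  structure(p, class = "ant_params")
}

#' @export
print.ant_params <- function(x, ...) {
  cat("Arena Langevin model parameters (cm, s):\n")
  cat(sprintf("  sigma_T = %.4g cm/s   sigma_L = %.4g cm/s\n",
              x$sigma_T, x$sigma_L))
  cat(sprintf("  tau_D   = %.4g s      v0      = %.4g cm/s   dt = %.5g s\n",
              x$tau_D, x$v0, x$dt))
  invisible(x)
}

#' Derived scales of the model
#'
#' Computes the emergent speed scale \eqn{v_\infty}, localization length
#' \eqn{\ell}, impulse anisotropy \eqn{\alpha} and dimensionless drive
#' \eqn{u_0}:
#' \deqn{v_\infty^2 = \sigma_L^2 \tau_D / (2\Delta t), \quad
#'       \ell = v_\infty \tau_D, \quad
#'       \alpha = (\sigma_L^2 - \sigma_T^2)/\sigma_L^2, \quad
#'       u_0 = v_0 / v_\infty.}
#' \eqn{v_\infty} is the half-width of the equilibrium speed distribution
#' around its shoulder and \eqn{\ell} the distance over which an ant remains
#' localized before turning around.
#'
#' @param params An [model_params()] object.
#' @return An object of class `ant_scales` with fields `v_inf` (cm/s), `ell`
#'   (cm), `alpha` (dimensionless) and `u0` (dimensionless).
#' @examples
#' derive_scales(model_params()) # v_inf ~ 2.54 cm/s, ell ~ 1.40 cm, alpha 0.36
#' @export
derive_scales <- function(params) {
  stopifnot(inherits(params, "ant_params"))
  if (params$sigma_L <= 0)
    stop("invalid parameter 'sigma_L': must be > 0 to derive scales",
         call. = FALSE)
  v_inf <- sqrt(params$sigma_L^2 * params$tau_D / (2 * params$dt))
  structure(list(v_inf = v_inf,
                 ell = v_inf * params$tau_D,
                 alpha = (params$sigma_L^2 - params$sigma_T^2) / params$sigma_L^2,
                 u0 = params$v0 / v_inf),
            class = "ant_scales")
}

#' @export
print.ant_scales <- function(x, ...) {
  cat(sprintf("v_inf = %.4f cm/s   ell = %.4f cm   alpha = %.4f   u0 = %.4f\n",
              x$v_inf, x$ell, x$alpha, x$u0))
  invisible(x)
}

#' Shoulder speed of the equilibrium velocity distribution
#'
#' The equilibrium speed distribution of the unbounded model has a
#' ring-shaped plateau ("shoulder") that peaks at
#' \deqn{v_s = \frac{v_0 + v_\infty\sqrt{(v_0/v_\infty)^2 + 4\alpha}}{2},}
#' the positive root of \eqn{u^2 - u_0 u - \alpha = 0} in units of
#' \eqn{v_\infty}. With isotropic impulses (\eqn{\alpha = 0}) it collapses to
#' \eqn{v_s = v_0}.
#'
#' @inheritParams derive_scales
#' @return Shoulder speed in cm/s.
#' @examples
#' shoulder_speed(model_params()) # ~ 6.65 cm/s
#' @export
shoulder_speed <- function(params) {
  s <- derive_scales(params)
  disc <- s$u0^2 + 4 * s$alpha
  if (disc < 0)
    stop("no real shoulder speed: u0^2 + 4*alpha < 0", call. = FALSE)
  (params$v0 + s$v_inf * sqrt(disc)) / 2
}
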