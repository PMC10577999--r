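#' Square arena geometry
#'
#' The arena is the square `|x| < L/2, |y| < L/2` centered on the origin.
#' In `"stop"` mode a proposed position outside the arena is replaced by the
#' nearest boundary point and the exiting normal velocity component is set to
#' zero; in `"periodic"` mode there are no walls (positions are recorded
#' unwrapped, which keeps finite-difference velocities exact) and the model
#' behaves as in an unbounded homogeneous arena.
#'
#' @param L Side length in cm.
#' @param mode `"stop"` or `"periodic"`.
#' @return An object of class `ant_arena`.
#' @export
arena <- function(L = 30, mode = c("stop", "periodic")) {
  mode <- match.arg(mode)
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("arena side length L must be a positive number", call. = FALSE)
  structure(list(L = L, mode = mode), class = "ant_arena")
}

#' @export
print.ant_arena <- function(x, ...) {
  cat(sprintf("Square arena: L = %g cm, %s boundary\n", x$L, x$mode))
  invisible(x)
}

#' Deterministic force on a model ant
#'
#' The force combines a linear drag and a constant forward drive,
#' \deqn{F(v) = -v/\tau_D + (v_0/\tau_D)\,\hat d,}
#' where \eqn{\hat d} is the direction of motion when the speed is positive
#' and the persistent body heading when the ant is at rest (the drive
#' direction is undefined by the velocity alone at `v = 0`). Drag and drive
#' balance at speed `v0`.
#'
#' @param velocity Numeric length-2 velocity vector (cm/s).
#' @param heading Unit-length heading used when the speed is zero.
#' @param params An [model_params()] object.
#' @return Numeric length-2 force vector (cm/s^2).
#' @examples
#' p <- model_params()
#' ant_force(c(p$v0, 0), c(1, 0), p) # zero: drag balances drive
#' @export
ant_force <- function(velocity, heading, params) {
  stopifnot(inherits(params, "ant_params"), length(velocity) == 2L,
            length(heading) == 2L)
  sp <- sqrt(sum(velocity^2))
  d <- if (sp > 0) velocity / sp else heading
  -velocity / params$tau_D + (params$v0 / params$tau_D) * d
}

#' Project an exiting proposal back onto the arena boundary
#'
#' Implements the stop-at-wall protocol: a proposed position outside the open
#' arena is replaced by the nearest point of the closed arena (which lies on
#' its boundary) and the velocity component normal to each crossed wall is
#' set to zero, leaving the tangential component untouched. A corner proposal
#' is clamped to the corner and both components are zeroed.
#'
#' @param proposal Numeric length-2 proposed position (cm), outside the arena.
#' @param velocity Numeric length-2 velocity to be projected (cm/s).
#' @param arena An [arena()] object (stop mode).
#' @return List with `position`, `velocity`, and `walls` (character subset of
#'   `c("+x", "-x", "+y", "-y")` identifying the contacted wall(s)).
#' @examples
#' boundary_project(c(15.7, 3), c(4, 2), arena(30)) # (15, 3), (0, 2)
#' @export
boundary_project <- function(proposal, velocity, arena) {
  stopifnot(inherits(arena, "ant_arena"), length(proposal) == 2L,
            length(velocity) == 2L)
  half <- arena$L / 2
  if (all(abs(proposal) <= half))
    stop("boundary_project called with an interior point", call. = FALSE)
  pos <- proposal
  vel <- velocity
  walls <- character(0)
  if (abs(proposal[1]) > half) {
    pos[1] <- sign(proposal[1]) * half
    vel[1] <- 0
    walls <- c(walls, if (proposal[1] > 0) "+x" else "-x")
  }
  if (abs(proposal[2]) > half) {
    pos[2] <- sign(proposal[2]) * half
    vel[2] <- 0
    walls <- c(walls, if (proposal[2] > 0) "+y" else "-y")
  }
  list(position = pos, velocity = vel, walls = walls)
}

# walls touched by a position lying (exactly) on the boundary
walls_at <- function(position, half) {
  walls <- character(0)
  if (position[1] >= half) walls <- c(walls, "+x")
  if (position[1] <= -half) walls <- c(walls, "-x")
  if (position[2] >= half) walls <- c(walls, "+y")
  if (position[2] <= -half) walls <- c(walls, "-y")
  walls
}

#' Advance a single ant state by one time step
#'
#' Reference (pure R) implementation of the discrete Langevin update
#' \deqn{x(t+\Delta t) = x(t) + v(t)\Delta t, \qquad
#'       v(t+\Delta t) = v(t) + F(v)\Delta t + q,}
#' with the impulse \eqn{q = q_T\,\hat z\times\hat h + q_L\,\hat h} drawn in
#' the frame of the current heading (\eqn{q_T} from the Laplace law with sd
#' `sigma_T`, then \eqn{q_L} with sd `sigma_L`, both zero mean, consuming two
#' uniforms from R's RNG in that order — the same draw order as the compiled
#' simulator, so chained calls reproduce [simulate_trajectory()] exactly).
#'
#' If the previous step ended on a wall (`wall_flag`), the sign of the
#' transverse impulse is reflected so that the turn points away from that
#' wall: with the boundary on the ant's right, the applied \eqn{q_T} is
#' positive (a left turn). For a symmetric zero-mean law this sign reflection
#' is distributionally identical to redrawing. A head-on heading (transverse
#' direction parallel to the wall) leaves the draw unconstrained. At corners
#' the rule is applied per wall in the fixed order `+x, -x, +y, -y` and the
#' last applicable wall decides.
#'
#' @param state List with `position`, `velocity` (length-2 numerics) and
#'   `heading` (unit length-2 vector).
#' @param params An [model_params()] object.
#' @param arena An [arena()] object.
#' @param wall_flag Character vector of walls the ant currently touches
#'   (subset of `c("+x","-x","+y","-y")`), or `NULL` when in the interior.
#' @return List with the new `state`, the applied impulse components `q_T`
#'   and `q_L`, and `wall_flag` for the next step.
#' @export
step_ant <- function(state, params, arena, wall_flag = NULL) {
  stopifnot(inherits(params, "ant_params"), inherits(arena, "ant_arena"))
  half <- arena$L / 2
  h <- state$heading
  eT <- c(-h[2], h[1])
  q_T <- qlaplace_sd(stats::runif(1), 0, params$sigma_T)
  q_L <- qlaplace_sd(stats::runif(1), 0, params$sigma_L)
  if (arena$mode == "stop" && length(wall_flag)) {
    outward <- list("+x" = c(1, 0), "-x" = c(-1, 0),
                    "+y" = c(0, 1), "-y" = c(0, -1))
    req <- 0
    for (w in c("+x", "-x", "+y", "-y")) {
      if (!w %in% wall_flag) next
      d <- sum(eT * outward[[w]])
      if (abs(d) > 1e-12) req <- if (d < 0) 1 else -1
    }
    if (req != 0) q_T <- req * abs(q_T)
  }
  proposal <- state$position + state$velocity * params$dt
  v_new <- state$velocity + ant_force(state$velocity, h, params) * params$dt +
    q_T * eT + q_L * h
  if (arena$mode == "stop" && any(abs(proposal) > half)) {
    pr <- boundary_project(proposal, v_new, arena)
    proposal <- pr$position
    v_new <- pr$velocity
  }
  flag <- if (arena$mode == "stop") walls_at(proposal, half) else character(0)
  sp <- sqrt(sum(v_new^2))
  if (sp > 0) h <- v_new / sp
  list(state = list(position = proposal, velocity = v_new, heading = h),
       q_T = q_T, q_L = q_L, wall_flag = flag)
}

#' Simulate one model-ant trajectory
#'
#' Runs the discrete Langevin update for `T/dt` steps in the given arena,
#' using the compiled core. By default the ant starts at the origin with zero
#' velocity and a uniformly random body heading, mirroring the protocol used
#' to generate the model ensembles; the recorded equilibrium statistics do
#' not depend on this choice.
#'
#' @param params An [model_params()] object.
#' @param arena An [arena()] object.
#' @param T Duration in seconds; must be a multiple of `params$dt`.
#' @param seed Integer seed; a fixed seed reproduces the trajectory exactly.
#' @param init Optional list with `position`, `velocity`, `heading` to
#'   override the default initial state.
#' @return An object of class `ant_trajectory`: list with `positions`
#'   (`(T/dt + 1) x 2` matrix, cm), `dt`, `seed`, `arena`, `params` and
#'   `wall_contacts`. Velocities are not stored; derive them with
#'   [velocities()].
#' @examples
#' tr <- simulate_trajectory(model_params(), arena(30), T = 10, seed = 1)
#' dim(tr$positions)
#' @export
simulate_trajectory <- function(params, arena, T, seed, init = NULL) {
  stopifnot(inherits(params, "ant_params"), inherits(arena, "ant_arena"))
  n_steps <- T / params$dt
  if (T <= 0 || abs(n_steps - round(n_steps)) > 1e-8)
    stop("T must be a positive multiple of dt", call. = FALSE)
  n_steps <- as.integer(round(n_steps))
  set.seed(seed)
  if (is.null(init)) {
    theta <- stats::runif(1, 0, 2 * pi)
    init <- list(position = c(0, 0), velocity = c(0, 0),
                 heading = c(cos(theta), sin(theta)))
  }
  res <- cpp_simulate_2d(n_steps, params$dt, params$tau_D, params$v0,
                         params$sigma_T, params$sigma_L, arena$L,
                         arena$mode == "periodic",
                         c(init$position, init$velocity, init$heading))
  structure(list(positions = res$positions, dt = params$dt, seed = seed,
                 arena = arena, params = params,
                 wall_contacts = res$wall_contacts),
            class = "ant_trajectory")
}

#' @export
print.ant_trajectory <- function(x, ...) {
  cat(sprintf("Ant trajectory: %d points, dt = %.5g s, %s arena L = %g cm\n",
              nrow(x$positions), x$dt, x$arena$mode, x$arena$L))
  invisible(x)
}

# deterministic per-trajectory stream seed; keeps values in 32-bit range
derive_stream_seed <- function(base_seed, j) {
  (as.double(base_seed) %% 2147483647 + 1000003 * as.double(j)) %% 2147483647
}

#' Simulate an ensemble of independent trials
#'
#' Trajectory `j` is seeded deterministically from `(base_seed, j)`, so
#' ensembles are reproducible and trials are generated from separate streams.
#' The experimental protocol this emulates is 60 trials of 4500 steps at
#' `dt = 1/15` s (300 s each) in a 30 cm arena.
#'
#' @inheritParams simulate_trajectory
#' @param N Number of trials.
#' @param base_seed Integer seed for the ensemble.
#' @param init Optional initial state applied to every trial.
#' @return An object of class `ant_ensemble`: list with `trajectories`,
#'   `params`, `arena`, `base_seed`.
#' @export
simulate_ensemble <- function(params, arena, T, N, base_seed, init = NULL) {
  stopifnot(N >= 1)
  trajectories <- lapply(seq_len(N), function(j)
    simulate_trajectory(params, arena, T, derive_stream_seed(base_seed, j),
                        init = init))
  structure(list(trajectories = trajectories, params = params, arena = arena,
                 base_seed = base_seed),
            class = "ant_ensemble")
}

#' @export
print.ant_ensemble <- function(x, ...) {
  n <- length(x$trajectories)
  steps <- nrow(x$trajectories[[1]]$positions) - 1L
  wc <- sum(vapply(x$trajectories, `[[`, numeric(1), "wall_contacts"))
  cat(sprintf("Ant ensemble: %d trials x %d steps (%s arena L = %g cm), %d wall contacts\n",
              n, steps, x$arena$mode, x$arena$L, wc))
  invisible(x)
}

#' Simulate the one-dimensional reduction of the model
#'
#' A scalar version of the dynamics used to study the near-wall density
#' analytically: \eqn{v \leftarrow v + \Delta t\,(v_0\,\mathrm{sign}(v) -
#' v)/\tau_D + q_L} with \eqn{q_L} from the Laplace law with sd `sigma_L`,
#' stop walls at \eqn{\pm L/2} (velocity zeroed on contact) and the first
#' post-contact impulse directed inward. The `sign(v)` drive is the natural
#' scalar analogue of the forward drive; at a wall (`v = 0`) the drive
#' vanishes until an impulse sets the ant moving.
#'
#' @inheritParams simulate_ensemble
#' @param L Domain length (cm), walls at `±L/2`.
#' @return An object of class `ant_ensemble_1d`: list of numeric position
#'   series plus `params`, `L`, `base_seed`.
#' @export
simulate_1d <- function(params, L, T, N, base_seed) {
  stopifnot(inherits(params, "ant_params"), N >= 1, L > 0)
  n_steps <- T / params$dt
  if (T <= 0 || abs(n_steps - round(n_steps)) > 1e-8)
    stop("T must be a positive multiple of dt", call. = FALSE)
  n_steps <- as.integer(round(n_steps))
  trajectories <- lapply(seq_len(N), function(j) {
    set.seed(derive_stream_seed(base_seed, j))
    res <- cpp_simulate_1d(n_steps, params$dt, params$tau_D, params$v0,
                           params$sigma_L, L, 0, 0)
    structure(list(positions = res$positions, dt = params$dt, L = L,
                   wall_contacts = res$wall_contacts),
              class = "ant_trajectory_1d")
  })
  structure(list(trajectories = trajectories, params = params, L = L,
                 base_seed = base_seed),
            class = "ant_ensemble_1d")
}
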