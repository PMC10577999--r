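test_that("force law balances drag and drive", {
  p <- fitted_params()
  expect_equal(ant_force(c(p$v0, 0), c(1, 0), p), c(0, 0))
  # at rest the drive acts along the persistent heading
  expect_equal(ant_force(c(0, 0), c(1, 0), p), c(p$v0 / p$tau_D, 0))
  # at twice the drive speed the net force opposes motion with |F| = v0/tau_D
  F2 <- ant_force(c(0, 2 * p$v0), c(0, 1), p)
  expect_equal(F2, c(0, -p$v0 / p$tau_D))
})

test_that("noise-free dynamics follow the closed-form geometric relaxation", {
  p0 <- model_params(sigma_T = 0, sigma_L = 0)
  # single Euler step from speed 1: hand arithmetic
  tr <- simulate_trajectory(p0, arena(1e6), T = 1, seed = 1,
                            init = list(position = c(0, 0),
                                        velocity = c(1, 0),
                                        heading = c(1, 0)))
  v <- velocities(tr)
  expect_equal(v[2, 1], 1.6424242424242423, tolerance = 1e-15)
  # v(n dt) = v0 + (1 - dt/tau_D)^n (v(0) - v0), to machine precision
  fx <- make_fixtures()
  vr <- velocities(fx$relaxation)
  n <- seq_len(nrow(vr)) - 1
  pred <- p0$v0 + (1 - p0$dt / p0$tau_D)^n * (1 - p0$v0)
  expect_equal(vr[, 1], pred, tolerance = 1e-12)
  expect_equal(max(abs(vr[, 2])), 0)
})

test_that("boundary projection implements the stop-at-wall protocol", {
  ar <- arena(30)
  r <- boundary_project(c(15.7, 3.0), c(4, 2), ar)
  expect_equal(r$position, c(15, 3.0))
  expect_equal(r$velocity, c(0, 2))
  expect_identical(r$walls, "+x")
  # corner proposal clamps to the corner and zeroes both components
  rc <- boundary_project(c(15.5, 15.2), c(3, 2), ar)
  expect_equal(rc$position, c(15, 15))
  expect_equal(rc$velocity, c(0, 0))
  expect_setequal(rc$walls, c("+x", "+y"))
  # head-on hit on the -x wall
  rh <- boundary_project(c(-16, 0), c(-5, 0), ar)
  expect_equal(rh$position, c(-15, 0))
  expect_equal(rh$velocity, c(0, 0))
  expect_error(boundary_project(c(1, 1), c(0, 0), ar), "interior")
})

test_that("first impulse after wall contact turns away from the wall", {
  p <- fitted_params()
  ar <- arena(30)
  # ant on the +x wall heading along +y: the boundary is on its right,
  # so the applied transverse impulse must be positive (a left turn)
  st <- list(position = c(15, 0), velocity = c(0, 4), heading = c(0, 1))
  set.seed(5)
  qT_right <- replicate(2000, step_ant(st, p, ar, wall_flag = "+x")$q_T)
  expect_true(all(qT_right > 0))
  # heading along -y puts the wall on the left: impulse must be negative
  st2 <- list(position = c(15, 0), velocity = c(0, -4), heading = c(0, -1))
  qT_left <- replicate(2000, step_ant(st2, p, ar, wall_flag = "+x")$q_T)
  expect_true(all(qT_left < 0))
  # without the flag both signs occur
  qT_free <- replicate(2000, step_ant(st, p, ar, wall_flag = NULL)$q_T)
  expect_true(any(qT_free > 0) && any(qT_free < 0))
})

test_that("R reference stepper reproduces the compiled trajectory", {
  p <- fitted_params()
  for (mode in c("stop", "periodic")) {
    ar <- arena(4, mode)  # tiny arena to force frequent wall handling
    n <- 300
    tr <- simulate_trajectory(p, ar, T = n * p$dt, seed = 77)
    set.seed(77)
    theta <- runif(1, 0, 2 * pi)
    st <- list(position = c(0, 0), velocity = c(0, 0),
               heading = c(cos(theta), sin(theta)))
    flag <- NULL
    pos <- matrix(0, n + 1, 2)
    for (i in seq_len(n)) {
      r <- step_ant(st, p, ar, flag)
      st <- r$state
      flag <- r$wall_flag
      pos[i + 1, ] <- st$position
    }
    expect_equal(pos, unname(tr$positions), tolerance = 1e-12)
  }
})

test_that("trajectories are deterministic given seeds and stay in the arena", {
  p <- fitted_params()
  ar <- arena(30)
  t1 <- simulate_trajectory(p, ar, T = 30, seed = 3)
  t2 <- simulate_trajectory(p, ar, T = 30, seed = 3)
  expect_identical(t1$positions, t2$positions)
  e1 <- simulate_ensemble(p, ar, T = 15, N = 4, base_seed = 9)
  e2 <- simulate_ensemble(p, ar, T = 15, N = 4, base_seed = 9)
  expect_identical(lapply(e1$trajectories, `[[`, "positions"),
                   lapply(e2$trajectories, `[[`, "positions"))
  expect_error(simulate_trajectory(p, ar, T = 0.1, seed = 1), "multiple")

  # containment over ~1e6 steps in a small arena (stop mode)
  ens <- simulate_ensemble(p, arena(10), T = 100000 * p$dt, N = 10,
                           base_seed = 31)
  for (tr in ens$trajectories)
    expect_true(all(abs(tr$positions) <= 5 + 1e-12))

  # the ensemble emulating the experiment: 60 trials x 4500 steps
  e60 <- simulate_ensemble(p, ar, T = 300, N = 2, base_seed = 1)
  expect_equal(nrow(e60$trajectories[[1]]$positions), 4501)
})

test_that("periodic-mode equilibrium is isotropic and init-independent", {
  p <- fitted_params()
  # direction histogram uniform: the travel direction decorrelates only over
  # ~50 steps within a trajectory, so the chi-square test is fed the final
  # velocity direction of many independent trials instead
  ens <- simulate_ensemble(p, arena(30, "periodic"), T = 20, N = 720,
                           base_seed = 17)
  v <- t(vapply(ens$trajectories, function(tr) {
    n <- nrow(tr$positions)
    (tr$positions[n, ] - tr$positions[n - 1, ]) / tr$dt
  }, numeric(2)))
  ang <- atan2(v[, 2], v[, 1]) %% (2 * pi)
  counts <- tabulate(findInterval(ang, seq(0, 2 * pi, length.out = 37),
                                  rightmost.closed = TRUE), nbins = 36)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  # interior speed distribution does not depend on the initial state
  ar <- arena(30)
  e1 <- simulate_ensemble(p, ar, T = 300, N = 50, base_seed = 100)
  e2 <- simulate_ensemble(p, ar, T = 300, N = 50, base_seed = 200,
                          init = list(position = c(14.9, 0),
                                      velocity = c(0, 0),
                                      heading = c(0, 1)))
  d <- ks_stat(interior_speeds(e1, burn = 100),
               stats::ecdf(interior_speeds(e2, burn = 100)))
  expect_lt(d, 0.02)
})

test_that("simulated speeds match the pre-point equilibrium law", {
  # oracle equivalence: periodic-mode samples against the corrected
  # closed-form speed density (see the methods vignette for why the
  # pre-point construction carries the -alpha weight)
  p <- fitted_params()
  ens <- simulate_ensemble(p, arena(30, "periodic"), T = 300, N = 50,
                           base_seed = 11)
  sp <- all_speeds(ens, burn = 150)
  cdf <- equilibrium_speed_cdf(derive_scales(p), anisotropy_sign = -1)
  expect_lt(ks_stat(sp, cdf), 0.01)
})

test_that("1D reduction: noise-free stop, wall pile-up, flat far field", {
  p0 <- model_params(sigma_T = 0, sigma_L = 0)
  # noise-free from rest: zero drive at v = 0, never moves
  x0 <- simulate_1d(p0, L = 10, T = 40, N = 1,
                    base_seed = 1)$trajectories[[1]]$positions
  expect_true(all(x0 == 0))
  # noise-free from v(0) = v0: uniform motion until wall contact, then at
  # rest forever (drag and drive balance exactly at v0)
  set.seed(1)
  xm <- antarena:::cpp_simulate_1d(900, p0$dt, p0$tau_D, p0$v0, 0, 10, 0,
                                   p0$v0)$positions
  hit <- which(xm >= 5)[1]
  expect_equal(diff(xm[1:hit])[1:(hit - 2)],
               rep(p0$v0 * p0$dt, hit - 2), tolerance = 1e-12)
  expect_true(all(xm[hit:length(xm)] == 5))

  p <- fitted_params()
  ens <- simulate_1d(p, L = 30, T = 2000, N = 6, base_seed = 23)
  ell <- derive_scales(p)$ell
  d <- unlist(lapply(ens$trajectories, function(tr)
    15 - abs(tr$positions[-(1:500)])))
  expect_true(all(d >= -1e-12))
  # density rises towards the wall within d < ell/2 ...
  near <- mean(d >= ell / 50 & d < ell / 8) / (ell / 8 - ell / 50)
  mid <- mean(d >= ell / 8 & d < ell / 2) / (ell / 2 - ell / 8)
  expect_gt(near, mid)
  # ... and is flat far from the walls (|x| < 5 cm)
  xs <- unlist(lapply(ens$trajectories, function(tr) tr$positions[-(1:500)]))
  h <- tabulate(findInterval(xs[abs(xs) < 5], seq(-5, 5, 1),
                             rightmost.closed = TRUE), nbins = 10)
  expect_lt(max(abs(h / mean(h) - 1)), 0.2)
})
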