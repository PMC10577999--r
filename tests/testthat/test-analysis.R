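test_that("velocities are forward differences of positions", {
  tr <- as_trajectory(rbind(c(0, 0), c(1, 0)), dt = 1 / 15)
  expect_equal(unname(velocities(tr)[1, ]), c(15, 0))
  tr2 <- as_trajectory(matrix(2, nrow = 5, ncol = 2), dt = 0.1)
  expect_true(all(velocities(tr2) == 0))
  expect_error(velocities(as_trajectory(rbind(c(0, 0)))), "at least 2")
})

test_that("velocity-change decomposition uses the left-positive frame", {
  dt <- 1
  # v = (1,0) -> (1,0.5): perpendicular change, a left turn
  tr <- as_trajectory(rbind(c(0, 0), c(1, 0), c(2, 0.5)), dt = dt)
  d <- decompose_dv(tr, strip_width = 3)
  expect_equal(d$dv_T, 0.5)
  expect_equal(d$dv_L, 0)
  # v = (1,0) -> (2,0): pure speed-up
  tr <- as_trajectory(rbind(c(0, 0), c(1, 0), c(3, 0)), dt = dt)
  d <- decompose_dv(tr)
  expect_equal(d$dv_T, 0)
  expect_equal(d$dv_L, 1)
  # v = (0,1) -> (0.5,1): a right turn in the cross-product frame
  tr <- as_trajectory(rbind(c(0, 0), c(0, 1), c(0.5, 2)), dt = dt)
  d <- decompose_dv(tr)
  expect_equal(d$dv_T, -0.5)
  expect_equal(d$dv_L, 0)

  # round trip: dv_T (z x v-hat) + dv_L v-hat rebuilds the vector difference
  p <- fitted_params()
  tr <- simulate_trajectory(p, arena(30), T = 30, seed = 21)
  vel <- diff(tr$positions) / tr$dt
  dv <- diff(vel)
  d <- decompose_dv(tr, speed_floor = 0.1)
  idx <- round(d$t / tr$dt) + 1L
  v <- vel[idx, ]
  sp <- sqrt(rowSums(v^2))
  eL <- v / sp
  rebuilt <- cbind(d$dv_T * (-eL[, 2]) + d$dv_L * eL[, 1],
                   d$dv_T * eL[, 1] + d$dv_L * eL[, 2])
  expect_equal(rebuilt, unname(dv[idx, ]), tolerance = 1e-12)
  # region tag follows the 3 cm rule on the position at time t
  pos_t <- tr$positions[idx, ]
  expect_identical(d$region == "interior",
                   unname(pmax(abs(pos_t[, 1]), abs(pos_t[, 2])) < 12))
})

test_that("per-bin fits recover a known generative law", {
  fx <- make_fixtures(3)
  sam <- fx$laplace_bins
  fT <- bin_and_fit(sam, "T", min_n = 200)
  expect_lt(abs(weighted.mean(fT$sigma, fT$n) - 1.00), 0.03)
  # transverse means are zero within ~3 standard errors (se ~ sigma/sqrt(n))
  expect_true(all(abs(fT$q_bar) < 3.5 * fT$sigma / sqrt(fT$n)))

  fL <- bin_and_fit(sam, "L", min_n = 200)
  # the longitudinal mean decreases with speed across the linear window
  win <- fL[fL$bin_center >= 3 & fL$bin_center <= 10, ]
  expect_lt(stats::cor(win$bin_center, win$q_bar), -0.95)
  ff <- fit_force_params(fL, dt = attr(sam, "dt"))
  expect_lt(abs(ff$tau_D_hat - 0.55) / 0.55, 0.10)
  expect_lt(abs(ff$v0_hat - 6.3) / 6.3, 0.05)

  expect_error(bin_and_fit(sam[1:50, ], "T", min_n = 200), "occupancy")
})

test_that("force fit inverts an exact linear mean at machine precision", {
  p <- fitted_params()
  centers <- seq(3.5, 9.5, by = 1)
  fits <- data.frame(bin_low = centers - 0.5, bin_high = centers + 0.5,
                     bin_center = centers, n = 1000,
                     q_bar = p$dt * (p$v0 - centers) / p$tau_D,
                     sigma = 1.25)
  class(fits) <- c("laplace_fits", "data.frame")
  ff <- fit_force_params(fits, dt = p$dt)
  expect_equal(ff$tau_D_hat, p$tau_D, tolerance = 1e-12)
  expect_equal(ff$v0_hat, p$v0, tolerance = 1e-12)
  # a rising mean carries no drag signal
  fits$q_bar <- rev(fits$q_bar)
  expect_error(fit_force_params(fits, dt = p$dt), "no drag signal")
  expect_error(fit_force_params(fits[1:2, ], dt = p$dt), "at least 3")
})

test_that("lag correlation: iid series, perfect recall, degeneracy", {
  set.seed(31)
  x <- rlaplace_sd(1e5, 0, 1)
  expect_lt(abs(as.numeric(lag_correlation(x, lag = 3))), 0.01)
  expect_equal(as.numeric(lag_correlation(x, lag = 0)), 1)
  expect_error(lag_correlation(rep(1, 100), lag = 3), "degenerate")
  expect_error(lag_correlation(x[1:4], lag = 3), "too short")
})

test_that("distribution maps normalize and respect square symmetry", {
  set.seed(41)
  # uniform synthetic positions: flat density within multinomial noise
  pos <- cbind(runif(6e4, -15, 15), runif(6e4, -15, 15))
  ens <- as_ensemble(list(as_trajectory(pos)))
  dm <- density_map(ens, bin = 1)
  expect_equal(sum(dm$values) * 1 * 1, 1, tolerance = 1e-9)
  mx <- marginal(dm, "x")
  expect_equal(sum(mx$density) * 1, 1, tolerance = 1e-9)
  counts <- mx$density * 6e4
  expect_true(max(abs(counts - 2000)) < 5 * sqrt(2000))

  # velocity maps normalize too
  p <- fitted_params()
  sim <- simulate_ensemble(p, arena(30), T = 60, N = 4, base_seed = 51)
  vm <- velocity_map(sim, "all", bin = 0.5)
  expect_equal(sum(vm$values) * 0.5 * 0.5, 1, tolerance = 1e-9)

  # rotating every trajectory by 90 degrees swaps the velocity marginals
  # (periodic mode, initial at-rest samples dropped: velocities then never
  # fall exactly on a bin edge, so the negated histogram reverses cleanly)
  sim <- simulate_ensemble(p, arena(30, "periodic"), T = 60, N = 4,
                           base_seed = 51)
  sim <- as_ensemble(lapply(sim$trajectories, function(tr)
    as_trajectory(tr$positions[-(1:5), ], dt = tr$dt, mode = "periodic")))
  rot <- as_ensemble(lapply(sim$trajectories, function(tr)
    as_trajectory(cbind(-tr$positions[, 2], tr$positions[, 1]), dt = tr$dt,
                  mode = "periodic")))
  vr <- velocity_map(rot, "all", bin = 0.5, vmax = 25)
  vo <- velocity_map(sim, "all", bin = 0.5, vmax = 25)
  expect_equal(marginal(vr, "y")$density, marginal(vo, "x")$density)
  expect_equal(marginal(vr, "x")$density, rev(marginal(vo, "y")$density))
})

test_that("near-wall exponent fitter is self-consistent", {
  set.seed(61)
  ell <- 1.4
  # draws with density proportional to d^(-2/3) on (0, ell/2]
  d <- (ell / 2) * runif(2e5)^3
  fit <- near_wall_exponent(d, ell = ell)
  expect_lt(abs(fit$exponent + 2 / 3), max(0.05, 3 * fit$se))
  # uniform draws carry no slope
  fit0 <- near_wall_exponent(runif(2e5, 0, ell), ell = ell)
  expect_lt(abs(fit0$exponent), 0.05)
  expect_error(near_wall_exponent(d[1:50], ell = ell), "insufficient")
})
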