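# parameters fitted to the tracked-ant data; used throughout the suite
fitted_params <- function() model_params(sigma_T = 1.00, sigma_L = 1.25,
                                         tau_D = 0.55, v0 = 6.3, dt = 1 / 15)

# two-sided Kolmogorov-Smirnov distance of a sample against a CDF function
ks_stat <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}

# interior finite-difference speeds of an ensemble (strip rule on the
# position at the start of each interval)
interior_speeds <- function(ensemble, strip_width = 3, burn = 0L) {
  half <- ensemble$arena$L / 2
  unlist(lapply(ensemble$trajectories, function(tr) {
    v <- diff(tr$positions) / tr$dt
    p <- tr$positions[seq_len(nrow(v)), , drop = FALSE]
    s <- sqrt(rowSums(v^2))
    keep <- pmax(abs(p[, 1]), abs(p[, 2])) < half - strip_width
    if (burn > 0L) keep[seq_len(min(burn, length(keep)))] <- FALSE
    s[keep]
  }), use.names = FALSE)
}

# all finite-difference speeds (periodic-mode ensembles have no walls)
all_speeds <- function(ensemble, burn = 0L) {
  unlist(lapply(ensemble$trajectories, function(tr) {
    v <- diff(tr$positions) / tr$dt
    s <- sqrt(rowSums(v^2))
    if (burn > 0L) s <- s[-seq_len(min(burn, length(s)))]
    s
  }), use.names = FALSE)
}

# build an ant_trajectory object from a bare position matrix (for synthetic
# analysis inputs)
as_trajectory <- function(positions, dt = 1 / 15, L = 30, mode = "stop") {
  structure(list(positions = positions, dt = dt, seed = NA,
                 arena = arena(L, mode), params = NULL, wall_contacts = NA),
            class = "ant_trajectory")
}

as_ensemble <- function(trajectories) {
  structure(list(trajectories = trajectories, params = NULL,
                 arena = trajectories[[1]]$arena, base_seed = NA),
            class = "ant_ensemble")
}
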