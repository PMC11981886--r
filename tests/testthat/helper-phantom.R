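# Shared fixture builders.  Everything is generated in code; no binary
# fixtures live in the repository.

# Small noiseless PGSE phantom (fast default for unit tests).
tiny_pgse <- function(grid = c(24, 24), noise_sd = 0, seed = 7,
                      kinetics = NULL) {
  cfg <- phantom_config(grid_size = grid, noise_sd = noise_sd,
                        regional_kinetics = kinetics, rng_seed = seed)
  simulate_pgse_latency_series(cfg)
}

# Uniform-kinetics phantom: all three bands share one parameter set
# (amplitude calibrated to realistic dip depth unless A = 0).
uniform_pgse <- function(params, grid = c(16, 16), noise_sd = 0, seed = 1) {
  if (params$A > 0) params <- mumri:::calibrate_twitch_amplitude(params)
  tiny_pgse(grid = grid, noise_sd = noise_sd, seed = seed,
            kinetics = list(superficial = params, deep = params,
                            aponeurosis = params))
}

# Condition + detect for one voxel of a phantom; returns landmarks.
detect_voxel <- function(sim, row, col, window = 1) {
  tr <- condition_trace(sim$series$data[row, col, ], sim$series$frame_times,
                        window = window)
  detect_landmarks(tr, estimate_baseline(tr))
}

# Independent brute-force landmark oracle: densely sample the tension
# model, differentiate numerically, and locate the two speed maxima and
# the tension peak.  Never calls the package's closed forms.
brute_force_landmarks <- function(t0, k, tau, A = 1, dt = 1e-3,
                                  t_max = NULL) {
  if (is.null(t_max)) t_max <- t0 + (k + sqrt(k)) * tau + 5 * tau
  tt <- seq(t0, t_max, by = dt)
  u <- (tt - t0) / tau
  f <- A * u^k * exp(-u)
  v <- diff(f) / dt
  tv <- (tt[-1] + tt[-length(tt)]) / 2
  speed <- abs(v)
  # local maxima of the numeric speed trace (tie-tolerant comparisons)
  n <- length(speed)
  pk <- which(speed[2:(n - 1)] > speed[1:(n - 2)] &
                speed[2:(n - 1)] >= speed[3:n]) + 1
  pk <- pk[order(speed[pk], decreasing = TRUE)][1:2]
  pk <- sort(pk)
  list(t_min1 = tv[pk[1]], t_min2 = tv[pk[2]],
       t_middle = tt[which.max(f)])
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("max |err| = %g (tol %g)",
                              max(abs(actual - expected)), tol))
}
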