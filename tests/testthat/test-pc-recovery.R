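# Phase-contrast reduction and recovery-curve modelling.

test_that("phase_to_velocity maps phase linearly and flags aliasing", {
  v <- phase_to_velocity(matrix(pi / 2, 2, 2), venc = 6)
  expect_equal(v$velocity, matrix(3, 2, 2))
  expect_false(v$aliased)
  expect_equal(phase_to_velocity(0, venc = 6)$velocity, 0)
  expect_warning(va <- phase_to_velocity(1.1 * pi, venc = 6), "aliasing")
  expect_true(va$aliased)
  expect_error(phase_to_velocity(matrix(0, 2, 2)), "venc")
})

test_that("find_peak_latency locates the velocity-profile peak", {
  # velocity latency scan: kernel peaking at 60 ms
  lat <- seq(0, 150, by = 5)
  gs <- 12
  mask <- muscle_mask(matrix(TRUE, gs, gs))
  prof <- 4 * exp(-(lat - 60)^2 / (2 * 15^2))
  arr <- array(rep(prof, each = gs * gs), dim = c(gs, gs, length(lat)))
  ser <- dynamic_series(arr, lat, time_unit = "ms", modality = "pc_velocity")
  pk <- find_peak_latency(ser, mask)
  expect_close(pk$latency, 60, 2.5)
  # symmetric kernel, symmetric axis: refined peak at the centre
  expect_equal(pk$latency, 60, tolerance = 1e-6)
  # tie between two equal maxima goes to the earlier latency with warning
  prof2 <- rep(0, length(lat)); prof2[c(5, 10)] <- 1
  arr2 <- array(rep(prof2, each = gs * gs), dim = c(gs, gs, length(lat)))
  ser2 <- dynamic_series(arr2, lat, time_unit = "ms",
                         modality = "pc_velocity")
  expect_warning(pk2 <- find_peak_latency(ser2, mask), "earliest")
  expect_close(pk2$latency, lat[5], 2.5)
  # all-zero series errors
  zed <- dynamic_series(array(0, dim = c(gs, gs, 12)), seq_len(12) * 5,
                        time_unit = "ms", modality = "pc_velocity")
  expect_error(find_peak_latency(zed, mask), "all-zero")
})

test_that("extract_cycle_peaks: counts, constants, trailing frames", {
  sim <- simulate_pc_recovery_series(n_dynamics = 600, noise_sd = 0)
  curve <- extract_cycle_peaks(sim$series, sim$mask)
  expect_equal(nrow(curve$samples), 120)
  expect_true(all(diff(curve$samples$t) > 0))
  # floor(frames / cycle) samples, incomplete trailing cycle dropped
  sub <- sim$series
  sub$data <- sub$data[, , 1:23]
  sub$frame_times <- sub$frame_times[1:23]
  sub$frame_meta <- sub$frame_meta[1:23, ]
  expect_warning(c23 <- extract_cycle_peaks(sub, sim$mask), "incomplete")
  expect_equal(nrow(c23$samples), 4)
  # constant series: every sample equals the constant
  gs <- dim(sim$series$data)[1:2]
  const <- dynamic_series(array(2.5, dim = c(gs, 24)), seq_len(24),
                          time_unit = "s", modality = "pc_velocity")
  allmask <- muscle_mask(matrix(TRUE, gs[1], gs[2]))
  cc <- extract_cycle_peaks(const, allmask, cycle_length = 4)
  expect_true(all(cc$samples$v == 2.5))
  # cycle longer than the series errors
  expect_error(extract_cycle_peaks(const, allmask, cycle_length = 30),
               "exceeds")
  # noiseless phantom samples track the true curve within 1% once the
  # per-cycle relative velocity change is small against the kernel taper
  sel <- sim$truth$v_true > 1
  expect_lt(max(abs(curve$samples$v[sel] - sim$truth$v_true[sel]) /
                  sim$truth$v_true[sel]), 0.01)
})

test_that("normalize_curve scales to end-recovery velocity and is idempotent", {
  sim <- simulate_pc_recovery_series(noise_sd = 0)
  curve <- extract_cycle_peaks(sim$series, sim$mask)
  nc <- normalize_curve(curve)
  expect_equal(nc$normalization, "end_normalized")
  n_tail <- ceiling(0.1 * nrow(nc$samples))
  expect_equal(mean(tail(nc$samples$v, n_tail)), 1, tolerance = 1e-12)
  # plateau of the normalised phantom curve is within 1% of 1
  expect_close(tail(nc$samples$v, 5), rep(1, 5), 0.01)
  nc2 <- normalize_curve(nc)
  expect_equal(nc2$samples$v, nc$samples$v, tolerance = 1e-12)
  # short or non-positive curves are rejected
  short <- curve; short$samples <- curve$samples[1:3, ]
  expect_error(normalize_curve(short), ">= 5")
  neg <- curve; neg$samples$v <- -neg$samples$v
  expect_error(normalize_curve(neg), "non-positive")
})

test_that("Gompertz fit recovers generating parameters exactly without noise", {
  t <- seq(10, 1200, length.out = 120)
  y <- 5 * exp(-3 * exp(-0.01 * t)) - 0.5
  fit <- fit_gompertz(data.frame(t = t, v = y))
  expect_true(fit$converged)
  expect_equal(fit$a, 5, tolerance = 1e-6)
  expect_equal(fit$b, 3, tolerance = 1e-6)
  expect_equal(fit$c, 0.01, tolerance = 1e-6)
  expect_equal(fit$d, 0.5, tolerance = 1e-6)
  expect_gt(fit$adjusted_r2, 1 - 1e-10)
  # fitted curve monotone non-decreasing on a dense grid (b, c > 0)
  dense <- fit$fitted(seq(0, 1500, by = 1))
  expect_true(all(diff(dense) >= -1e-12))
  # constant curve is flagged degenerate
  expect_warning(fc <- fit_gompertz(data.frame(t = t, v = rep(2, 120))),
                 "unidentifiable")
  expect_false(fc$converged)
  expect_error(fit_gompertz(data.frame(t = 1:5, v = 1:5)), ">= 8")
})

test_that("Gompertz estimator bias shrinks with the noise level", {
  t <- seq(10, 1200, length.out = 120)
  y0 <- 5 * exp(-3 * exp(-0.01 * t)) - 0.5
  thm_true <- half_max_time(list(a = 5, b = 3, c = 0.01, d = 0.5))
  errs <- sapply(c(0.25, 0.05, 0.005), function(sdn) {
    set.seed(99)
    median(replicate(15, {
      f <- fit_gompertz(data.frame(t = t, v = y0 + rnorm(120, 0, sdn)))
      abs(f$t_half_max - thm_true) / thm_true
    }))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)
})

test_that("half-max closed forms: identities and numeric agreement", {
  # y(0) already at half maximum when b = log 2
  expect_equal(half_max_time(list(a = 1, b = log(2), c = 1, d = 0)), 0,
               tolerance = 1e-12)
  expect_equal(half_max_time(list(a = 1, b = 1, c = 1, d = 0)),
               -log(log(2)), tolerance = 1e-12)
  # doubling c halves the half-max time when d = 0
  t1 <- half_max_time(list(a = 2, b = 4, c = 0.01, d = 0))
  t2 <- half_max_time(list(a = 2, b = 4, c = 0.02, d = 0))
  expect_equal(t2, t1 / 2, tolerance = 1e-12)
  # numeric root-finder agreement, both definitions
  for (defn in c("plateau_half", "range_half")) {
    for (pars in list(c(5, 3, 0.01, 0.5), c(1, 8, 0.05, 0.2),
                      c(10, 0.9, 0.002, 0))) {
      a <- pars[1]; b <- pars[2]; c <- pars[3]; d <- pars[4]
      thm <- half_max_time(list(a = a, b = b, c = c, d = d),
                           definition = defn)
      target <- if (defn == "plateau_half") (a - d) / 2
                else ((a * exp(-b) - d) + (a - d)) / 2
      root <- uniroot(function(T) a * exp(-b * exp(-c * T)) - d - target,
                      c(-2000 / c, 2000 / c), tol = 1e-13 / c)$root
      expect_close(thm, root, 1e-9 / c)
    }
  }
  # level outside the curve range errors
  expect_error(half_max_time(list(a = 1, b = 1, c = 1, d = 1.5)),
               "plateau_half undefined")
})

test_that("end-to-end pipeline recovers T_half-max within 10% at 5% noise", {
  truth <- list(a = 5, b = 3, c = 0.01, d = 0)
  thm_true <- half_max_time(truth)
  errs <- sapply(1:5, function(seed) {
    sim <- simulate_pc_recovery_series(gompertz = truth, noise_sd = 0.25,
                                       rng_seed = seed)
    fit <- fit_gompertz(extract_cycle_peaks(sim$series, sim$mask))
    abs(fit$t_half_max - thm_true) / thm_true
  })
  expect_true(all(errs < 0.10))
})

test_that("mono-exponential recovery fit recovers kPCr", {
  t <- seq(5, 600, by = 5)
  # exact samples recovered to solver precision
  y <- 10 - 5 * exp(-0.0107 * t)
  f <- fit_monoexponential(t, y)
  expect_true(f$converged)
  expect_equal(f$k_pcr, 0.0107, tolerance = 1e-7)
  expect_equal(f$half_time, log(2) / 0.0107, tolerance = 1e-6)
  expect_equal(f$half_time, 64.8, tolerance = 0.01)  # control-scale ~65 s
  # Monte-Carlo: 5% noise (of the recovery amplitude), kPCr = 0.02,
  # median relative error < 5%
  set.seed(4)
  errs <- replicate(100, {
    yn <- (10 - 5 * exp(-0.02 * t)) + rnorm(length(t), 0, 0.25)
    abs(fit_monoexponential(t, yn)$k_pcr - 0.02) / 0.02
  })
  expect_lt(median(errs), 0.05)
  # non-recovering series flagged
  expect_warning(nr <- fit_monoexponential(t, 10 - 0.01 * t),
                 "does not recover")
  expect_false(nr$recovering)
  expect_error(fit_monoexponential(1:5, 1:5), ">= 6")
})
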