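# Landmark detection, metrics, parametric maps, histograms, category maps.

test_that("baseline estimation: mean, SD, and sample-count guard", {
  tr <- list(time = seq(-45, 50, by = 5), signal = rep(100, 20))
  bl <- estimate_baseline(tr)
  expect_equal(bl$mean, 100)
  expect_equal(bl$sd, 0)
  expect_equal(bl$n, sum(tr$time < 0))
  # hand computation: {98, 100, 102} repeated has mean 100, SD 2 (approx)
  tr2 <- list(time = c(-6:-1, 1, 2), signal = c(rep(c(98, 100, 102), 2), 5, 5))
  bl2 <- estimate_baseline(tr2)
  expect_equal(bl2$mean, 100)
  expect_equal(bl2$sd, sd(c(98, 100, 102, 98, 100, 102)))
  # explicit window override
  bl3 <- estimate_baseline(tr, window = c(-45, -20))
  expect_equal(bl3$n, sum(tr$time >= -45 & tr$time <= -20))
  # too few baseline samples
  expect_error(estimate_baseline(list(time = c(-2, -1, 1, 2, 3),
                                      signal = rep(1, 5))), ">= 5")
})

test_that("landmarks on noiseless phantom voxels match analytic truth", {
  p <- twitch_kinetics_params(t0 = 10, k = 2, tau = 50)
  sim <- uniform_pgse(p)
  vox <- which(sim$mask$mask, arr.ind = TRUE)
  truth <- mumri:::twitch_landmark_truth(p)
  for (i in c(1, nrow(vox) %/% 2, nrow(vox))) {
    lm <- detect_voxel(sim, vox[i, 1], vox[i, 2], window = 1)
    expect_true(lm$valid)
    expect_close(lm$t_min1, truth$t_min1, 2.5)
    expect_close(lm$t_middle, truth$t_middle, 2.5)
    expect_close(lm$t_min2, truth$t_min2, 2.5)
    expect_close(lm$t_start, truth$t_start, 2.5)
  }
})

test_that("landmark failure modes and ordering guard", {
  flat <- list(time = seq(-45, 400, by = 0.5),
               signal = rep(100, length(seq(-45, 400, by = 0.5))))
  bl <- estimate_baseline(flat)
  lf <- detect_landmarks(flat, bl)
  expect_false(lf$valid)
  expect_equal(lf$failure_reason, "no_onset")
  # single-dip trace: one minimum only
  tt <- seq(-45, 400, by = 0.5)
  dip <- 100 - 30 * exp(-(tt - 100)^2 / (2 * 25^2))
  ld <- detect_landmarks(list(time = tt, signal = dip),
                         estimate_baseline(list(time = tt, signal = dip)))
  expect_false(ld$valid)
  expect_equal(ld$failure_reason, "lt_two_minima")
  # invalid landmarks propagate through compute_metrics
  m <- compute_metrics(ld)
  expect_true(is.na(m$t_rise) && is.na(m$t_contract) && is.na(m$t_half_relax))
  expect_equal(m$failure_reason, "lt_two_minima")
})

test_that("metrics are exact differences of landmarks", {
  lm <- structure(list(t_start = 10, t_min1 = 49, t_middle = 120,
                       t_min2 = 190, valid = TRUE,
                       failure_reason = NA_character_),
                  class = "twitch_landmarks")
  m <- compute_metrics(lm)
  expect_equal(m$t_rise, 39)
  expect_equal(m$t_contract, 110)
  expect_equal(m$t_half_relax, 141)
})

test_that("landmarks are invariant to adding a constant to the signal", {
  p <- twitch_kinetics_params(t0 = 10, k = 2.3, tau = 55)
  sim <- uniform_pgse(p, grid = c(12, 12), noise_sd = 1, seed = 3)
  vox <- which(sim$mask$mask, arr.ind = TRUE)[1, ]
  tr <- condition_trace(sim$series$data[vox[1], vox[2], ],
                        sim$series$frame_times)
  lm1 <- detect_landmarks(tr, estimate_baseline(tr))
  tr2 <- tr; tr2$signal <- tr$signal + 57.3
  lm2 <- detect_landmarks(tr2, estimate_baseline(tr2))
  expect_equal(unclass(lm1)[1:4], unclass(lm2)[1:4], tolerance = 1e-12)
})

test_that("map_metrics recovers regional truth on a two-region phantom", {
  cal <- mumri:::calibrate_twitch_amplitude
  kin <- list(superficial = cal(twitch_kinetics_params(t0 = 10, k = 2,
                                                       tau = 40)),
              deep        = cal(twitch_kinetics_params(t0 = 10, k = 2,
                                                       tau = 80)),
              aponeurosis = cal(twitch_kinetics_params(t0 = 10, k = 2,
                                                       tau = 80)))
  sim <- tiny_pgse(grid = c(24, 24), kinetics = kin)
  maps <- map_metrics(sim$series, sim$mask, window = 1)
  expect_equal(maps$excluded_fraction, 0)
  for (metric in c("t_rise", "t_contract", "t_half_relax")) {
    mm <- maps[[metric]]
    for (reg in c("superficial", "deep")) {
      sel <- sim$truth$region == reg
      est <- mapply(function(r, cc) mm$values[r, cc],
                    sim$truth$row[sel], sim$truth$col[sel])
      expect_close(mean(est), mean(sim$truth[[metric]][sel]), 2.5)
    }
  }
  # mean over valid voxels only; invalid voxels carry NA, never zero
  expect_false(any(mm$values[!sim$mask$mask] == 0, na.rm = TRUE))
})

test_that("all-baseline series yields 100% invalid voxels with a warning", {
  sim <- uniform_pgse(twitch_kinetics_params(t0 = 10, k = 2, tau = 50, A = 0),
                      grid = c(12, 12))
  expect_warning(maps <- map_metrics(sim$series, sim$mask), "invalid")
  expect_equal(maps$excluded_fraction, 1)
  expect_equal(maps$t_rise$n_valid, 0)
})

test_that("healthy-range scale check: default phantom lands on control scale", {
  sim <- tiny_pgse(grid = c(32, 32), noise_sd = 0)
  maps <- map_metrics(sim$series, sim$mask)
  # control-scale values: T_rise ~ 39 ms, T_contract ~ 116 ms
  expect_gt(maps$t_rise$mean, 39 * 0.7)
  expect_lt(maps$t_rise$mean, 39 * 1.4)
  expect_gt(maps$t_contract$mean, 116 * 0.7)
  expect_lt(maps$t_contract$mean, 116 * 1.4)
})

test_that("landmark detection is robust at 2% gaussian noise", {
  sim <- tiny_pgse(grid = c(44, 44), noise_sd = 2, seed = 12)  # 2% of S0
  expect_gte(nrow(sim$truth), 500)
  maps <- map_metrics(sim$series, sim$mask)
  for (metric in c("t_rise", "t_contract", "t_half_relax")) {
    est <- mapply(function(r, cc) maps[[metric]]$values[r, cc],
                  sim$truth$row, sim$truth$col)
    err <- abs(est - sim$truth[[metric]])
    expect_lt(median(err, na.rm = TRUE), 5)
  }
})

test_that("histogram conserves counts, integrates to one, finds modes", {
  sim <- tiny_pgse(grid = c(24, 24))
  maps <- map_metrics(sim$series, sim$mask, window = 1)
  h <- build_histogram(maps$t_contract)
  expect_equal(sum(h$counts), maps$t_contract$n_valid)
  expect_length(h$counts, 50)
  # density integrates to ~1 over its support (trapezoid)
  dx <- diff(h$density$x)
  integral <- sum(dx * (head(h$density$y, -1) + tail(h$density$y, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  # bimodal synthetic map: modes recovered within 10 ms
  vals <- matrix(NA_real_, 40, 40)
  set.seed(11)
  vals[1:40, 1:20] <- rnorm(800, 100, 5)
  vals[1:40, 21:40] <- rnorm(800, 200, 5)
  mm <- mumri:::new_metric_map(vals, !is.na(vals), "t_contract")
  hb <- build_histogram(mm)
  d <- hb$density
  pk <- which(diff(sign(diff(d$y))) == -2) + 1
  pk <- d$x[pk[order(d$y[pk], decreasing = TRUE)][1:2]]
  expect_close(sort(pk), c(100, 200), 10)
  # pooling across maps sums the counts
  hp <- build_histogram(list(mm, mm))
  expect_equal(sum(hp$counts), 2 * mm$n_valid)
  # single-value map occupies one bin
  one <- mumri:::new_metric_map(matrix(150, 3, 3), matrix(TRUE, 3, 3), "m")
  h1 <- build_histogram(one)
  expect_equal(sum(h1$counts > 0), 1)
  expect_equal(sum(h1$counts), 9)
})

test_that("category maps partition valid voxels in both modes", {
  vals <- matrix(c(90, 120, 170, 230, NA, 95, 140, 210, 160),
                 3, 3)
  valid <- !is.na(vals)
  mm <- mumri:::new_metric_map(vals, valid, "t_contract")
  cm <- threshold_map(mm, mode = "fixed_edges")
  expect_equal(cm$classes[1:4], c(1L, 2L, 3L, 4L))   # the spec'd example
  expect_equal(sum(cm$counts), sum(valid))
  expect_true(all(is.na(cm$classes[!valid])))
  # all values <= 100 go to class 1 (empty classes allowed)
  low <- mumri:::new_metric_map(matrix(c(80, 90, 99, 60), 2, 2),
                                matrix(TRUE, 2, 2), "m")
  expect_warning(cl <- threshold_map(low, mode = "fixed_edges"),
                 "outside the data range")
  expect_true(all(cl$classes == 1L))
  # equal_span splits [80, 280] at 130/180/230
  es <- mumri:::new_metric_map(matrix(c(80, 130, 180, 280), 2, 2),
                               matrix(TRUE, 2, 2), "m")
  ce <- threshold_map(es, mode = "equal_span")
  expect_equal(ce$edges[2:4], c(130, 180, 230), tolerance = 1e-9)
  expect_equal(sum(ce$counts), 4)
})
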