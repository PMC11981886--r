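# Forward-model phantom: a leg cross-section with an elliptical
# tibialis-anterior region split into three concentric kinetic bands
# (superficial fast, deep slower, peri-aponeurosis slowest), driven by the
# analytic twitch model so every simulated voxel carries exact landmark
# ground truth.

#' Phantom configuration
#'
#' @param grid_size Image grid, `c(rows, cols)`.
#' @param muscle_ellipse Ellipse descriptor `list(center = c(row, col),
#'   semiaxes = c(a_row, a_col))` in pixel units; defaults to a centred
#'   ellipse filling ~40% of the grid.
#' @param regional_kinetics Named list with elements `superficial`, `deep`,
#'   `aponeurosis`, each a [twitch_kinetics_params()].  Defaults emulate a
#'   healthy tibialis anterior: contraction times on the 100-160 ms scale,
#'   shortest superficially, longest around the central aponeurosis.
#' @param latency_axis Stimulus-to-readout offsets (ms), strictly
#'   increasing.  The default `seq(-45, 400, by = 5)` reproduces the
#'   90-acquisition gating of the latency protocol (stimulus from 45 ms
#'   after to 400 ms before readout, 5 ms steps).
#' @param noise_sd Additive noise SD in signal units (default 2% of the
#'   superficial baseline).
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param rng_seed Integer seed; a fixed seed makes every simulator output
#'   bit-reproducible.
#'
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_size = c(64, 64),
                           muscle_ellipse = NULL,
                           regional_kinetics = NULL,
                           latency_axis = seq(-45, 400, by = 5),
                           noise_sd = NULL,
                           noise_model = c("gaussian", "rician"),
                           rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(grid_size) == 2L, all(grid_size >= 8))
  if (is.unsorted(latency_axis, strictly = TRUE))
    stop("latency axis must be strictly increasing")
  if (is.null(muscle_ellipse))
    muscle_ellipse <- list(center = (grid_size + 1) / 2,
                           semiaxes = grid_size * 0.32)
  if (is.null(regional_kinetics))
    regional_kinetics <- list(
      superficial = calibrate_twitch_amplitude(
        twitch_kinetics_params(t0 = 10, k = 2.3, tau = 45)),
      deep        = calibrate_twitch_amplitude(
        twitch_kinetics_params(t0 = 10, k = 2.3, tau = 55)),
      aponeurosis = calibrate_twitch_amplitude(
        twitch_kinetics_params(t0 = 10, k = 2.3, tau = 70)))
  stopifnot(all(c("superficial", "deep", "aponeurosis") %in%
                  names(regional_kinetics)))
  for (p in regional_kinetics)
    stopifnot(inherits(p, "twitch_kinetics_params"))
  if (is.null(noise_sd))
    noise_sd <- 0.02 * regional_kinetics$superficial$S0
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(grid_size = as.integer(grid_size),
                 muscle_ellipse = muscle_ellipse,
                 regional_kinetics = regional_kinetics,
                 latency_axis = latency_axis,
                 noise_sd = noise_sd,
                 noise_model = noise_model,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_config")
}

# Run expr with a private RNG state seeded from `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

add_noise <- function(x, sd, model) {
  if (sd == 0) return(x)
  if (model == "gaussian") {
    x + stats::rnorm(length(x), 0, sd)
  } else {
    # magnitude of a complex signal with iid gaussian channel noise
    sqrt((x + stats::rnorm(length(x), 0, sd))^2 +
           stats::rnorm(length(x), 0, sd)^2)
  }
}

# Region label matrix: 0 outside muscle; 1 superficial, 2 deep,
# 3 peri-aponeurosis, by normalised elliptical radius (outer third band
# superficial, core aponeurosis).
phantom_regions <- function(config) {
  gs <- config$grid_size
  ce <- config$muscle_ellipse$center
  ax <- config$muscle_ellipse$semiaxes
  r <- outer(seq_len(gs[1]), rep(1, gs[2])) - ce[1]
  c_ <- outer(rep(1, gs[1]), seq_len(gs[2])) - ce[2]
  rho <- sqrt((r / ax[1])^2 + (c_ / ax[2])^2)
  lab <- matrix(0L, gs[1], gs[2])
  lab[rho <= 1] <- 1L
  lab[rho <= 2 / 3] <- 2L
  lab[rho <= 1 / 3] <- 3L
  lab
}

region_names <- c("superficial", "deep", "aponeurosis")

#' Simulate a PGSE latency series with ground truth
#'
#' Generates a magnitude latency scan: per voxel the signal at latency `l`
#' (time since stimulus at readout, ms) is
#' `S0 * exp(-beta * |v(l)|) + noise`, with `v` the analytic twitch
#' velocity of the voxel's region.  Frames at negative latency (stimulus
#' after readout) carry pure baseline.
#'
#' @param config A [phantom_config()].
#'
#' @return A list with `series` (a [dynamic_series()]), `mask`
#'   (a [muscle_mask()]), `regions` (integer label matrix), and `truth`
#'   (data frame of per-voxel true landmark times and metrics, ms).
#' @export
simulate_pgse_latency_series <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  gs <- config$grid_size
  lab <- phantom_regions(config)
  lat <- config$latency_axis
  nf <- length(lat)
  S0_bg <- config$regional_kinetics$superficial$S0

  arr <- array(S0_bg, dim = c(gs[1], gs[2], nf))
  # per-region signal profiles over the latency axis
  profiles <- lapply(config$regional_kinetics, function(p) {
    v <- twitch_velocity(pmax(lat, 0), p)
    v[lat < 0] <- 0
    p$S0 * exp(-p$beta * abs(v))
  })
  for (reg in 1:3) {
    idx <- which(lab == reg)
    if (!length(idx)) next
    prof <- profiles[[region_names[reg]]]
    for (f in seq_len(nf)) {
      frame <- arr[, , f]
      frame[idx] <- prof[f]
      arr[, , f] <- frame
    }
  }
  arr <- with_seed(config$rng_seed,
                   array(add_noise(arr, config$noise_sd, config$noise_model),
                         dim = dim(arr)))

  vox <- which(lab > 0, arr.ind = TRUE)
  truth <- do.call(rbind, lapply(seq_len(nrow(vox)), function(i) {
    reg <- lab[vox[i, 1], vox[i, 2]]
    p <- config$regional_kinetics[[region_names[reg]]]
    lt <- twitch_landmark_truth(p)
    data.frame(row = vox[i, 1], col = vox[i, 2],
               region = region_names[reg],
               t_start = lt$t_start, t_min1 = lt$t_min1,
               t_middle = lt$t_middle, t_min2 = lt$t_min2,
               t_rise = lt$t_rise, t_contract = lt$t_contract,
               t_half_relax = lt$t_half_relax)
  }))

  series <- dynamic_series(arr, lat, time_unit = "ms",
                           modality = "pgse_magnitude")
  list(series = series,
       mask = muscle_mask(lab > 0, label = "TA"),
       regions = lab,
       truth = truth)
}

# Unimodal latency-response kernel for cyclic phase-contrast sampling:
# Gaussian in the latency offset with 30 ms full width at half maximum,
# normalised to 1 at the peak.
latency_kernel <- function(offset_ms, fwhm_ms = 30) {
  sigma <- fwhm_ms / (2 * sqrt(2 * log(2)))
  exp(-offset_ms^2 / (2 * sigma^2))
}

# Gompertz recovery curve y(x) = a*exp(-b*exp(-c*(x - x0))) - d.
gompertz_value <- function(x, a, b, c, d = 0, x0 = 0) {
  a * exp(-b * exp(-c * (x - x0))) - d
}

#' Simulate a cyclic phase-contrast recovery series
#'
#' Emulates cyclic sampling of a twitch-velocity peak during post-exercise
#' recovery: each cycle visits latency offsets around the expected peak
#' (default -10 ... +10 ms, 5 ms steps) and the peak amplitude follows a
#' Gompertz time course `V(t) = a*exp(-b*exp(-c*t)) - d`.  A frame acquired
#' at wall time `t` with offset `o` holds
#' `V(t) * g(o - drift * t) + noise`, with `g` a Gaussian latency-response
#' kernel (30 ms FWHM).
#'
#' @param gompertz Named list/vector with `a` (cm/s), `b`, `c` (1/s), `d`
#'   (cm/s); defaults `a = 5, b = 3, c = 0.01, d = 0`: the post-fatigue
#'   curve starts at `a*exp(-b)` (~0.25 cm/s, near zero) and velocities
#'   stay non-negative, as speed data must.
#' @param offsets Latency offsets of one cycle (ms).
#' @param n_dynamics Number of frames (default 600; with the default cycle
#'   of 5 this yields 120 peak-velocity measurements).
#' @param frame_period Seconds between frames (default 2 s, so 600 frames
#'   span 1200 s).
#' @param drift Peak-latency drift (ms per second of recovery), default 0.
#' @param noise_sd Additive velocity noise SD (cm/s).
#' @param grid_size Image grid for the synthetic frames.
#' @param rng_seed Integer seed.
#'
#' @return A list with `series` (pc_velocity [dynamic_series()] over wall
#'   time, with per-frame cycle index and offset in `frame_meta`), `mask`,
#'   and `truth` (data frame: cycle, time `t` at cycle midpoint, true peak
#'   velocity `v_true`; attribute `peak_left_window` flags drift carrying
#'   the peak outside the sampled offsets).
#' @export
simulate_pc_recovery_series <- function(gompertz = list(a = 5, b = 3,
                                                        c = 0.01, d = 0),
                                        offsets = seq(-10, 10, by = 5),
                                        n_dynamics = 600,
                                        frame_period = 2,
                                        drift = 0,
                                        noise_sd = 0.25,
                                        grid_size = c(16, 16),
                                        rng_seed = 1L) {
  stopifnot(n_dynamics >= length(offsets), frame_period > 0, noise_sd >= 0)
  g <- gompertz
  stopifnot(all(c("a", "b", "c", "d") %in% names(g)))
  cyc_len <- length(offsets)
  if (n_dynamics %% cyc_len != 0)
    warning("n_dynamics not divisible by cycle length; trailing frames form an incomplete cycle")

  i <- seq_len(n_dynamics)
  t_wall <- i * frame_period                 # s since end of exercise
  cycle <- (i - 1) %/% cyc_len + 1L
  off <- offsets[(i - 1) %% cyc_len + 1L]
  v_peak <- gompertz_value(t_wall, g$a, g$b, g$c, g$d)
  v_frame <- v_peak * latency_kernel(off - drift * t_wall)

  # uniform velocity over an elliptical muscle; still water outside
  gs <- as.integer(grid_size)
  ce <- (gs + 1) / 2
  ax <- gs * 0.35
  r <- outer(seq_len(gs[1]), rep(1, gs[2])) - ce[1]
  c_ <- outer(rep(1, gs[1]), seq_len(gs[2])) - ce[2]
  inmask <- (r / ax[1])^2 + (c_ / ax[2])^2 <= 1
  arr <- array(0, dim = c(gs[1], gs[2], n_dynamics))
  for (f in i) {
    frame <- matrix(0, gs[1], gs[2])
    frame[inmask] <- v_frame[f]
    arr[, , f] <- frame
  }
  arr <- with_seed(rng_seed, {
    if (noise_sd > 0) arr + array(stats::rnorm(length(arr), 0, noise_sd),
                                  dim = dim(arr)) else arr
  })

  n_cycles <- n_dynamics %/% cyc_len
  t_mid <- vapply(seq_len(n_cycles),
                  function(cc) mean(t_wall[cycle == cc]), numeric(1))
  truth <- data.frame(cycle = seq_len(n_cycles), t = t_mid,
                      v_true = gompertz_value(t_mid, g$a, g$b, g$c, g$d))
  # peak latency at end of recovery relative to sampled window
  max_shift <- abs(drift) * max(t_wall)
  attr(truth, "peak_left_window") <- max_shift > max(abs(offsets))
  if (attr(truth, "peak_left_window"))
    warning("latency drift carries the velocity peak outside the sampled window")

  meta <- data.frame(frame = i, time_s = t_wall, cycle = cycle,
                     latency_offset_ms = off)
  series <- dynamic_series(arr, t_wall, time_unit = "s",
                           modality = "pc_velocity", frame_meta = meta)
  list(series = series, mask = muscle_mask(inmask, label = "TA"),
       truth = truth, gompertz = g)
}

#' Simulate a stimulation-current ramp series
#'
#' Emulates the setup scan used to choose the stimulation current: PGSE
#' frames acquired while the current steps up, with the mean in-muscle
#' signal dropping along a response curve.
#'
#' @param config A [phantom_config()] (grid, ellipse, baseline, noise).
#' @param currents Strictly increasing stimulation currents (mA); must be
#'   non-empty and start at/near zero so a baseline frame exists.
#' @param response Function `f(current) -> signal fraction of baseline`
#'   (non-increasing, in (0, 1]); default a logistic drop centred at 13 mA
#'   with floor 0.2.
#'
#' @return A list with `series` (frame axis = current, stored in
#'   `frame_meta$current_mA`), `mask`, and `truth` (list: `crossing_found`,
#'   `i_67` the continuous-response 67% crossing in mA or `NA`).
#' @export
simulate_current_ramp <- function(config = phantom_config(),
                                  currents = seq(0, 20, by = 1),
                                  response = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (length(currents) == 0L) stop("`currents` must be non-empty")
  if (is.unsorted(currents, strictly = TRUE))
    stop("`currents` must be strictly increasing")
  if (is.null(response))
    response <- function(I) 0.2 + 0.8 / (1 + exp((I - 13) / 1.5))
  frac <- response(currents)
  if (any(diff(frac) > 1e-12)) stop("response must be non-increasing in current")

  gs <- config$grid_size
  lab <- phantom_regions(config)
  S0 <- config$regional_kinetics$superficial$S0
  nf <- length(currents)
  arr <- array(S0, dim = c(gs[1], gs[2], nf))
  for (f in seq_len(nf)) {
    frame <- arr[, , f]
    frame[lab > 0] <- S0 * frac[f]
    arr[, , f] <- frame
  }
  arr <- with_seed(config$rng_seed,
                   array(add_noise(arr, config$noise_sd, config$noise_model),
                         dim = dim(arr)))

  # ground-truth crossing from the continuous response curve
  target <- 0.67
  if (min(frac) > target) {
    truth <- list(crossing_found = FALSE, i_67 = NA_real_)
  } else if (frac[1] <= target) {
    truth <- list(crossing_found = TRUE, i_67 = currents[1])
  } else {
    i_67 <- stats::uniroot(function(I) response(I) - target,
                           range(currents), tol = 1e-9)$root
    truth <- list(crossing_found = TRUE, i_67 = i_67)
  }

  meta <- data.frame(frame = seq_len(nf), current_mA = currents)
  series <- dynamic_series(arr, seq_len(nf) - 1, time_unit = "s",
                           modality = "pgse_magnitude", frame_meta = meta)
  list(series = series, mask = muscle_mask(lab > 0, label = "TA"),
       truth = truth)
}
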