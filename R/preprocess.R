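# Upstream conditioning: frame registration, per-voxel trace smoothing and
# resampling, and stimulation-current selection from a setup ramp.

# Translate an image by (dr, dc) pixels with bilinear interpolation;
# out-of-field samples replicate the nearest edge.
shift_image <- function(img, shift) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(seq_len(nr) - shift[1], 1), nr)
  c_ <- pmin(pmax(seq_len(nc) - shift[2], 1), nc)
  r0 <- floor(r); r1 <- pmin(r0 + 1, nr); fr <- r - r0
  c0 <- floor(c_); c1 <- pmin(c0 + 1, nc); fc <- c_ - c0
  w00 <- outer(1 - fr, 1 - fc); w01 <- outer(1 - fr, fc)
  w10 <- outer(fr, 1 - fc);     w11 <- outer(fr, fc)
  img[r0, c0, drop = FALSE] * w00 + img[r0, c1, drop = FALSE] * w01 +
    img[r1, c0, drop = FALSE] * w10 + img[r1, c1, drop = FALSE] * w11
}

# Subpixel translation estimate of `moving` relative to `fixed` by FFT
# cross-correlation: if moving(x) = fixed(x - d), returns d = c(dr, dc).
# Full spectral whitening (classical phase correlation) is deliberately
# avoided: smooth magnitude images concentrate energy at low frequencies,
# and whitened high-frequency bins contribute only interpolation/noise
# phase that swamps the correlogram.  The unwhitened correlation peaks at
# the true lag (Cauchy-Schwarz) and its smooth apex suits parabolic
# sub-pixel refinement.
phase_correlate <- function(fixed, moving) {
  nr <- nrow(fixed); nc <- ncol(fixed)
  Fa <- stats::fft(fixed)
  Fb <- stats::fft(moving)
  R <- Fb * Conj(Fa)
  corr <- Re(stats::fft(R, inverse = TRUE)) / (nr * nc)
  pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]

  refine <- function(i, n, along) {
    # parabola through the peak and its wrapped neighbours
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    y0 <- along[im]; y1 <- along[i]; y2 <- along[ip]
    den <- y0 - 2 * y1 + y2
    if (abs(den) < .Machine$double.eps) return(0)
    max(-0.5, min(0.5, 0.5 * (y0 - y2) / den))
  }
  dr_frac <- refine(pk[1], nr, corr[, pk[2]])
  dc_frac <- refine(pk[2], nc, corr[pk[1], ])
  dr <- pk[1] - 1 + dr_frac
  dc <- pk[2] - 1 + dc_frac
  if (dr > nr / 2) dr <- dr - nr
  if (dc > nc / 2) dc <- dc - nc
  c(dr, dc)
}

#' Register a dynamic series to a reference frame
#'
#' Aligns every frame to the reference by subpixel phase-correlation
#' translation (the default, pluggable engine).  Frames whose estimated
#' displacement exceeds `max_displacement` are flagged as diverged and left
#' untouched so downstream steps can exclude them.
#'
#' @param series A [dynamic_series()] with at least two frames.
#' @param reference Index of the reference frame (default 1, the first
#'   image of the time series).
#' @param method Registration engine; only `"phase_correlation"` is built
#'   in.
#' @param max_displacement Displacement cap (pixels) beyond which a frame
#'   is flagged as a registration failure (default 10).
#'
#' @return A list with `series` (registered), and `displacements`
#'   (data frame: frame, dr, dc, magnitude, excluded).
#' @export
register_series <- function(series, reference = 1L,
                            method = "phase_correlation",
                            max_displacement = 10) {
  stopifnot(inherits(series, "dynamic_series"))
  nf <- n_frames(series)
  if (nf < 2L) stop("registration needs at least 2 frames")
  if (reference < 1L || reference > nf) stop("reference frame out of range")
  method <- match.arg(method, "phase_correlation")

  ref <- series$data[, , reference]
  out <- series$data
  disp <- data.frame(frame = seq_len(nf), dr = 0, dc = 0,
                     magnitude = 0, excluded = FALSE)
  for (f in seq_len(nf)) {
    if (f == reference) next
    d <- phase_correlate(ref, series$data[, , f])
    mag <- sqrt(sum(d^2))
    disp$dr[f] <- d[1]; disp$dc[f] <- d[2]; disp$magnitude[f] <- mag
    if (mag > max_displacement) {
      disp$excluded[f] <- TRUE
      next
    }
    if (mag > 1e-3)
      out[, , f] <- shift_image(series$data[, , f], -d)
  }
  reg <- series
  reg$data <- out
  list(series = reg, displacements = disp)
}

#' Condition a per-voxel trace
#'
#' Moving-average smoothing followed by piecewise-linear resampling to a
#' uniform fine grid (default 0.5 ms).  The smoothing window shrinks at the
#' trace boundaries so no samples are fabricated, and the output grid spans
#' the input latency range exactly.
#'
#' @param values Signal values, one per frame.
#' @param times Strictly increasing frame times (ms).
#' @param window Moving-average window in frames (default 3; centred, odd
#'   windows recommended).
#' @param target_step Output grid step (ms), default 0.5.
#'
#' @return A list with `time` (uniform grid) and `signal`.
#' @export
condition_trace <- function(values, times, window = 3, target_step = 0.5) {
  n <- length(values)
  stopifnot(length(times) == n, window >= 1, target_step > 0)
  if (is.unsorted(times, strictly = TRUE))
    stop("latency axis must be strictly increasing")
  if (n < 2 * window)
    stop(sprintf("need at least %d samples for window %d", 2 * window, window))
  h <- (window - 1) %/% 2
  sm <- vapply(seq_len(n), function(i)
    mean(values[max(1, i - h):min(n, i + h)]), numeric(1))
  grid <- seq(times[1], times[n], by = target_step)
  if (grid[length(grid)] < times[n])
    grid <- c(grid, times[n])
  list(time = grid,
       signal = stats::approx(times, sm, xout = grid)$y)
}

#' Select the stimulation current from a setup ramp
#'
#' Finds the current at which the mean in-muscle signal first drops to a
#' stated fraction (default 67%) of the unstimulated baseline, taken as the
#' first (lowest-current) frame.  The crossing is linearly interpolated
#' between the bracketing tested currents (`interpolate = FALSE` snaps to
#' the first tested current at or below the fraction).  The result is
#' invariant to global rescaling of the signal.
#'
#' @param ramp A [dynamic_series()] whose `frame_meta$current_mA` carries
#'   the tested currents.
#' @param mask A [muscle_mask()] congruent with the ramp.
#' @param fraction Target signal fraction of baseline (default 0.67).
#' @param interpolate Interpolate between tested currents (default TRUE).
#'
#' @return An object of class `current_ramp_result`: `i_muscle` (mA or
#'   `NA`), `crossing_found`, and `signal_fraction_curve` (data frame of
#'   current and fraction).
#' @export
select_stimulation_current <- function(ramp, mask, fraction = 0.67,
                                       interpolate = TRUE) {
  stopifnot(inherits(ramp, "dynamic_series"),
            is.numeric(fraction), fraction > 0, fraction <= 1)
  check_mask_congruent(ramp, mask)
  if (is.null(ramp$frame_meta) || is.null(ramp$frame_meta$current_mA))
    stop("ramp series must carry frame_meta$current_mA")
  currents <- ramp$frame_meta$current_mA
  m <- frame_mask_summary(ramp, mask, stat = "mean", absolute = FALSE)
  baseline <- m[1]
  if (baseline <= 0) stop("non-positive baseline signal")
  frac <- m / baseline
  curve <- data.frame(current_mA = currents, signal_fraction = frac)

  k <- which(frac <= fraction)[1]
  if (is.na(k)) {
    res <- list(i_muscle = NA_real_, crossing_found = FALSE,
                signal_fraction_curve = curve, fraction = fraction)
  } else if (k == 1L || !interpolate) {
    res <- list(i_muscle = currents[k], crossing_found = TRUE,
                signal_fraction_curve = curve, fraction = fraction)
  } else {
    f0 <- frac[k - 1]; f1 <- frac[k]
    i_m <- currents[k - 1] +
      (f0 - fraction) / (f0 - f1) * (currents[k] - currents[k - 1])
    res <- list(i_muscle = i_m, crossing_found = TRUE,
                signal_fraction_curve = curve, fraction = fraction)
  }
  structure(res, class = "current_ramp_result")
}

#' @export
print.current_ramp_result <- function(x, ...) {
  if (x$crossing_found)
    cat(sprintf("Stimulation current: %.2f mA (%.0f%% signal fraction)\n",
                x$i_muscle, 100 * x$fraction))
  else
    cat(sprintf("No crossing: signal never reached %.0f%% of baseline\n",
                100 * x$fraction))
  invisible(x)
}
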