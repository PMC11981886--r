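# Voxel-wise twitch landmark detection on conditioned PGSE latency traces,
# the derived timing metrics, parametric maps, histograms, and thresholded
# category maps.
#
# Landmarks per trace: T_start, the onset of signal change (first time the
# signal falls below baseline mean - 3 * baseline SD); T_min1 and T_min2,
# the first two prominent signal minima after onset; T_middle, the point
# between the minima closest to the baseline level.  Metrics:
#   T_rise       = T_min1   - T_start
#   T_contract   = T_middle - T_start
#   T_half_relax = T_min2   - T_min1

#' Estimate the baseline of a conditioned trace
#'
#' The baseline is taken from all samples at negative time-since-stimulus
#' (stimulus after readout) unless an explicit window is given.
#'
#' @param trace A list with `time` (ms) and `signal`, as returned by
#'   [condition_trace()].
#' @param window Optional `c(lo, hi)` time window (ms) to use instead of
#'   all negative-time samples.
#'
#' @return A list with `mean`, `sd`, and `n`.
#' @export
estimate_baseline <- function(trace, window = NULL) {
  sel <- if (is.null(window)) trace$time < 0
         else trace$time >= window[1] & trace$time <= window[2]
  x <- trace$signal[sel]
  if (length(x) < 5L)
    stop(sprintf("need >= 5 baseline samples, got %d", length(x)))
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

# Indices of local minima of y (strict neighbours; plateaus take the first
# index of the flat stretch).
local_minima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] < y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j < n && y[j + 1L] > y[j]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Prominence of minima (scipy-style, on the inverted signal): for each
# candidate minimum, walk outwards until a sample lower than the minimum is
# met; the highest sample within each stretch is the shoulder, and the
# prominence is min(shoulder) - minimum value.
minima_prominence <- function(y, idx) {
  n <- length(y)
  vapply(idx, function(i) {
    v <- y[i]
    left <- if (i > 1) {
      lower <- which(y[1:(i - 1)] < v)
      lo <- if (length(lower)) max(lower) + 1L else 1L
      max(y[lo:(i - 1)])
    } else v
    right <- if (i < n) {
      lower <- which(y[(i + 1):n] < v)
      hi <- if (length(lower)) i + min(lower) - 1L else n
      max(y[(i + 1):hi])
    } else v
    min(left, right) - v
  }, numeric(1))
}

#' Detect twitch landmarks on a conditioned trace
#'
#' @param trace A list with `time` (uniform ms grid) and `signal`.
#' @param baseline Baseline summary from [estimate_baseline()].
#' @param onset_multiplier Onset threshold in baseline SDs (default 3).
#' @param prominence_multiplier Minimum-prominence threshold in baseline
#'   SDs (default 3).
#' @param fallback_window After-onset window (ms) searched for a global
#'   minimum when prominence finds exactly one minimum (default 300 ms).
#' @param refine_span Minimum half-span (ms) of the local least-squares
#'   cubic sub-sample refinement applied around each detected extremum
#'   (default 15 ms, three native latency steps).  The span widens to
#'   0.4x the local landmark spacing so broad, shallow extrema average
#'   noise over proportionally more samples.  Set to 0 to disable.
#'
#' @return An object of class `twitch_landmarks`: `t_start`, `t_min1`,
#'   `t_middle`, `t_min2` (ms, `NA` when invalid), `valid`, and
#'   `failure_reason` (`"no_onset"`, `"lt_two_minima"`,
#'   `"order_violation"`, or `NA` when valid).
#' @export
detect_landmarks <- function(trace, baseline, onset_multiplier = 3,
                             prominence_multiplier = 3,
                             fallback_window = 300, refine_span = 15) {
  stopifnot(baseline$sd >= 0)
  time <- trace$time; y <- trace$signal
  step <- time[2] - time[1]
  # sub-sample refinement: local least-squares cubic around the detected
  # grid extremum, taking the stationary point with matching curvature.
  # A cubic tracks the skewed dip shapes without the vertex bias a plain
  # parabola picks up on wide windows, so the span can grow with the
  # local landmark spacing to average noise on broad shallow extrema.
  refine_extremum <- function(vals, i, span) {
    if (refine_span <= 0) return(time[i])
    m <- max(2L, round(span / step))
    sel <- max(1L, i - m):min(length(vals), i + m)
    if (length(sel) < 7L) return(time[i])
    dx <- time[sel] - time[i]
    cf <- stats::lm.fit(cbind(1, dx, dx^2, dx^3), vals[sel])$coefficients
    if (!all(is.finite(cf))) return(time[i])
    v <- if (abs(cf[4]) < .Machine$double.eps) {
      if (abs(cf[3]) < .Machine$double.eps) return(time[i])
      -cf[2] / (2 * cf[3])
    } else {
      disc <- 4 * cf[3]^2 - 12 * cf[4] * cf[2]
      if (disc < 0) return(time[i])
      r <- c(-2 * cf[3] + sqrt(disc), -2 * cf[3] - sqrt(disc)) / (6 * cf[4])
      cand <- r[2 * cf[3] + 6 * cf[4] * r > 0]   # local minima of the cubic
      if (length(cand)) cand[which.min(abs(cand))] else r[which.min(abs(r))]
    }
    time[i] + max(-m * step, min(m * step, v))
  }
  thresh <- baseline$mean - onset_multiplier * baseline$sd

  fail <- function(reason) structure(
    list(t_start = NA_real_, t_min1 = NA_real_, t_middle = NA_real_,
         t_min2 = NA_real_, valid = FALSE, failure_reason = reason),
    class = "twitch_landmarks")

  onset_idx <- which(time >= 0 & y < thresh)[1]
  if (is.na(onset_idx)) return(fail("no_onset"))
  t_start <- time[onset_idx]

  post <- onset_idx:length(y)
  mins_rel <- local_minima(y[post])
  if (length(mins_rel)) {
    prom <- minima_prominence(y[post], mins_rel)
    keep <- prom >= prominence_multiplier * baseline$sd
    mins <- post[1] - 1L + mins_rel[keep]
  } else mins <- integer(0)

  if (length(mins) == 1L) {
    # global-minimum fallback: deepest sample in the post-onset window
    # beyond the single detected minimum
    win <- which(time > time[mins] & time <= time[mins] + fallback_window)
    if (length(win) > 2L) {
      g <- win[which.min(y[win])]
      if (g > mins + 1L && g < length(y)) mins <- c(mins, g)
    }
  }
  if (length(mins) < 2L) return(fail("lt_two_minima"))
  i1 <- mins[1]; i2 <- mins[2]
  # first dip is deep and sharp: the minimum span suffices; the second is
  # broad and shallow, so its span grows with the inter-minima spacing
  t_min1 <- refine_extremum(y, i1, refine_span)
  t_min2 <- refine_extremum(y, i2,
                            max(refine_span, 0.4 * (time[i2] - time[i1])))

  between <- (i1 + 1L):(i2 - 1L)
  if (length(between) < 1L) return(fail("order_violation"))
  dev <- abs(y - baseline$mean)
  im <- between[which.min(dev[between])]  # ties: earlier
  t_middle <- refine_extremum(dev, im, refine_span)

  if (!(t_start < t_min1 && t_min1 < t_middle && t_middle < t_min2))
    return(fail("order_violation"))
  structure(list(t_start = t_start, t_min1 = t_min1, t_middle = t_middle,
                 t_min2 = t_min2, valid = TRUE, failure_reason = NA_character_),
            class = "twitch_landmarks")
}

#' @export
print.twitch_landmarks <- function(x, ...) {
  if (x$valid)
    cat(sprintf("Landmarks (ms): T_start %.1f, T_min1 %.1f, T_middle %.1f, T_min2 %.1f\n",
                x$t_start, x$t_min1, x$t_middle, x$t_min2))
  else
    cat(sprintf("Invalid landmarks (%s)\n", x$failure_reason))
  invisible(x)
}

#' Compute twitch timing metrics from landmarks
#'
#' @param landmarks A `twitch_landmarks` object.
#'
#' @return A list with `t_rise`, `t_contract`, `t_half_relax` (ms; all
#'   `NA` with the `failure_reason` propagated when the landmarks are
#'   invalid).
#' @export
compute_metrics <- function(landmarks) {
  stopifnot(inherits(landmarks, "twitch_landmarks"))
  if (!landmarks$valid)
    return(list(t_rise = NA_real_, t_contract = NA_real_,
                t_half_relax = NA_real_, valid = FALSE,
                failure_reason = landmarks$failure_reason))
  list(t_rise = landmarks$t_min1 - landmarks$t_start,
       t_contract = landmarks$t_middle - landmarks$t_start,
       t_half_relax = landmarks$t_min2 - landmarks$t_min1,
       valid = TRUE, failure_reason = NA_character_)
}

new_metric_map <- function(values, valid, metric) {
  vv <- values[which(valid)]
  structure(list(values = values, valid = valid, metric = metric,
                 mean = if (length(vv)) mean(vv) else NA_real_,
                 sd = if (length(vv) > 1) stats::sd(vv) else NA_real_,
                 n_valid = length(vv)),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("Metric map '%s': %d valid voxels, mean %.1f ms (SD %.1f)\n",
              x$metric, x$n_valid, x$mean, x$sd))
  invisible(x)
}

#' Voxel-wise parametric maps of twitch metrics
#'
#' Runs the full per-voxel chain (conditioning, baseline estimation,
#' landmark detection, metric computation) over every in-mask voxel of a
#' registered PGSE latency series.
#'
#' @param series A pgse_magnitude [dynamic_series()] on a latency axis.
#' @param mask A congruent [muscle_mask()].
#' @param window Moving-average window (frames), default 3.
#' @param target_step Conditioning grid step (ms), default 0.5.
#' @param onset_multiplier,prominence_multiplier Detection thresholds in
#'   baseline SDs (default 3).
#'
#' @return A list of class `metric_map_set`: `t_rise`, `t_contract`,
#'   `t_half_relax` (each a `metric_map`), `excluded_fraction`, and
#'   `failure_reasons` (table).
#' @export
map_metrics <- function(series, mask, window = 3, target_step = 0.5,
                        onset_multiplier = 3, prominence_multiplier = 3) {
  stopifnot(inherits(series, "dynamic_series"))
  if (series$time_unit != "ms")
    stop("map_metrics expects a latency (ms) scan")
  check_mask_congruent(series, mask)
  idx <- which(mask$mask, arr.ind = TRUE)
  gs <- dim(series$data)[1:2]
  maps <- list(t_rise = matrix(NA_real_, gs[1], gs[2]),
               t_contract = matrix(NA_real_, gs[1], gs[2]),
               t_half_relax = matrix(NA_real_, gs[1], gs[2]))
  valid <- matrix(NA, gs[1], gs[2])
  reasons <- character(0)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; cc <- idx[i, 2]
    tr <- condition_trace(series$data[r, cc, ], series$frame_times,
                          window = window, target_step = target_step)
    bl <- estimate_baseline(tr)
    lm <- detect_landmarks(tr, bl, onset_multiplier = onset_multiplier,
                           prominence_multiplier = prominence_multiplier)
    mt <- compute_metrics(lm)
    valid[r, cc] <- mt$valid
    if (mt$valid) {
      maps$t_rise[r, cc] <- mt$t_rise
      maps$t_contract[r, cc] <- mt$t_contract
      maps$t_half_relax[r, cc] <- mt$t_half_relax
    } else reasons <- c(reasons, mt$failure_reason)
  }
  n_mask <- nrow(idx)
  excl <- length(reasons) / n_mask
  if (excl > 0.5)
    warning(sprintf("%.0f%% of in-mask voxels invalid", 100 * excl))
  structure(list(
    t_rise = new_metric_map(maps$t_rise, valid, "t_rise"),
    t_contract = new_metric_map(maps$t_contract, valid, "t_contract"),
    t_half_relax = new_metric_map(maps$t_half_relax, valid, "t_half_relax"),
    excluded_fraction = excl,
    failure_reasons = table(reasons)),
    class = "metric_map_set")
}

#' @export
print.metric_map_set <- function(x, ...) {
  for (m in c("t_rise", "t_contract", "t_half_relax")) print(x[[m]])
  cat(sprintf("Excluded: %.1f%% of in-mask voxels\n",
              100 * x$excluded_fraction))
  invisible(x)
}

#' Histogram and kernel-density summary of a metric map
#'
#' 50 equal-width bins over the pooled valid-voxel range, with a Gaussian
#' kernel density (Silverman bandwidth) fitted to the same values.
#'
#' @param map A `metric_map`, or a list of `metric_map`s to pool.
#' @param bins Number of bins (default 50).
#'
#' @return A list of class `histogram_summary`: `breaks`, `counts`,
#'   `density` (data frame `x`, `y`), and `n_valid`.
#' @export
build_histogram <- function(map, bins = 50) {
  maps <- if (inherits(map, "metric_map")) list(map) else map
  vals <- unlist(lapply(maps, function(m) m$values[which(m$valid)]))
  if (!length(vals)) stop("no valid voxels to pool")
  rng <- range(vals)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  dens <- if (length(vals) > 1 && stats::sd(vals) > 0)
    stats::density(vals, bw = "nrd0")
  else {
    # degenerate spread: a narrow Gaussian spike at the common value
    stats::density(vals, bw = max(1e-6, abs(vals[1]) * 1e-6))
  }
  structure(list(breaks = h$breaks, counts = h$counts,
                 density = data.frame(x = dens$x, y = dens$y),
                 n_valid = length(vals)),
            class = "histogram_summary")
}

#' Threshold a metric map into four timing categories
#'
#' `fixed_edges` mode uses the conventional contraction-time bands
#' `(min, 100]`, `(100, 150]`, `(150, 200]`, `(200, max]` ms;
#' `equal_span` splits the observed valid range into four equal intervals.
#' Intervals are half-open, right-closed.
#'
#' @param map A `metric_map`.
#' @param mode `"fixed_edges"` or `"equal_span"`.
#' @param edges Interior edges (3 values, ms) for `fixed_edges` mode;
#'   default `c(100, 150, 200)`.
#'
#' @return A list of class `category_map`: `classes` (integer matrix,
#'   1-4 or `NA`), `edges` (full 5-vector of class boundaries), `mode`,
#'   and `counts`.
#' @export
threshold_map <- function(map, mode = c("fixed_edges", "equal_span"),
                          edges = c(100, 150, 200)) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "metric_map"))
  vv <- map$values[which(map$valid)]
  if (!length(vv)) stop("no valid voxels")
  rng <- range(vv)
  if (mode == "fixed_edges") {
    stopifnot(length(edges) == 3L, !is.unsorted(edges, strictly = TRUE))
    hi <- max(rng[2], edges[3])
    if (hi <= edges[3]) hi <- edges[3] + 1e-9
    full <- c(min(rng[1], edges[1]) - 1e-9, edges, hi)
    if (edges[1] < rng[1] || edges[3] > rng[2])
      warning("some category edges fall outside the data range; empty classes allowed")
  } else {
    full <- seq(rng[1], rng[2], length.out = 5)
    full[1] <- full[1] - 1e-9
  }
  cls <- matrix(NA_integer_, nrow(map$values), ncol(map$values))
  ok <- which(map$valid)
  cls[ok] <- as.integer(cut(map$values[ok], breaks = full, labels = FALSE,
                            right = TRUE))
  structure(list(classes = cls, edges = full, mode = mode,
                 counts = tabulate(cls[ok], nbins = 4L)),
            class = "category_map")
}

#' @export
print.category_map <- function(x, ...) {
  cat(sprintf("Category map (%s): counts %s\n", x$mode,
              paste(x$counts, collapse = " / ")))
  invisible(x)
}
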