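# Cyclic phase-contrast reduction and fatigue-recovery modelling: velocity
# reconstruction from phase, peak-latency finding, per-cycle peak
# extraction, modified Gompertz fitting, time-to-half-maximum, and the
# companion mono-exponential phosphocreatine recovery fit.

#' Convert a phase frame to velocity
#'
#' Standard phase-contrast convention: a phase of pi maps to the velocity
#' encoding value, `v = phase / pi * venc`.
#'
#' @param phase Numeric matrix/array of phase values (radians).
#' @param venc Velocity encoding (cm/s), > 0.
#'
#' @return A list with `velocity` (cm/s, same shape) and `aliased`
#'   (TRUE when any `|phase| > pi`, i.e. velocities beyond the encoding
#'   range wrapped around).
#' @export
phase_to_velocity <- function(phase, venc) {
  if (missing(venc) || is.null(venc) || !is.numeric(venc) || venc <= 0)
    stop("`venc` (cm/s, > 0) is required")
  aliased <- any(abs(phase) > pi + 1e-12)
  if (aliased) warning("phase exceeds +/- pi: velocity aliasing likely")
  list(velocity = phase / pi * venc, aliased = aliased)
}

#' Find the latency of peak twitch velocity
#'
#' Scans a velocity latency series for the stimulus latency maximising the
#' mean in-mask speed, with quadratic sub-sample refinement around the
#' discrete peak.  Ties go to the earlier latency with a warning.
#'
#' @param series A pc_velocity [dynamic_series()] on a latency axis with
#'   at least 10 frames.
#' @param mask A congruent [muscle_mask()].
#' @param stat Per-frame in-mask summary, `"mean"` (default) or
#'   `"median"`.
#'
#' @return A list with `latency` (ms), `peak_speed` (cm/s), and `profile`
#'   (data frame of latency and mean speed).
#' @export
find_peak_latency <- function(series, mask, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(inherits(series, "dynamic_series"))
  if (n_frames(series) < 10L) stop("latency scan needs >= 10 frames")
  sp <- frame_mask_summary(series, mask, stat = stat, absolute = TRUE)
  if (all(sp == 0)) stop("all-zero velocity series")
  lat <- series$frame_times
  mx <- max(sp)
  peaks <- which(sp == mx)
  if (length(peaks) > 1L)
    warning("multiple equal velocity maxima; taking the earliest latency")
  k <- peaks[1]
  refined <- lat[k]
  if (k > 1L && k < length(sp)) {
    den <- sp[k - 1] - 2 * sp[k] + sp[k + 1]
    if (abs(den) > .Machine$double.eps) {
      frac <- 0.5 * (sp[k - 1] - sp[k + 1]) / den
      frac <- max(-0.5, min(0.5, frac))
      refined <- lat[k] + frac * mean(diff(lat))
    }
  }
  list(latency = refined, peak_speed = mx,
       profile = data.frame(latency = lat, speed = sp))
}

#' Extract per-cycle peak velocities from a cyclic recovery series
#'
#' Reduces a cyclic phase-contrast recovery scan to one peak-velocity
#' sample per complete cycle: the maximum over the cycle's frames of the
#' mean in-mask speed, timestamped at the cycle midpoint.  An incomplete
#' trailing cycle is dropped with a warning.
#'
#' @param series A pc_velocity [dynamic_series()] over wall time (s).
#' @param mask A congruent [muscle_mask()].
#' @param cycle_length Frames per cycle (default 5).
#' @param stat `"mean"` (default) or `"median"` in-mask speed summary.
#'
#' @return An object of class `recovery_curve`: data frame `samples`
#'   (`t` s, `v` cm/s, `frame` of the winning frame, `offset_ms` if the
#'   series carries per-frame latency offsets) plus a `normalization`
#'   state (`"raw"`).
#' @export
extract_cycle_peaks <- function(series, mask, cycle_length = 5,
                                stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(inherits(series, "dynamic_series"))
  nf <- n_frames(series)
  if (cycle_length > nf)
    stop(sprintf("cycle_length (%d) exceeds frame count (%d)",
                 cycle_length, nf))
  sp <- frame_mask_summary(series, mask, stat = stat, absolute = TRUE)
  n_cycles <- nf %/% cycle_length
  if (nf %% cycle_length != 0)
    warning(sprintf("dropping incomplete trailing cycle (%d frames)",
                    nf %% cycle_length))
  offs <- if (!is.null(series$frame_meta$latency_offset_ms))
    series$frame_meta$latency_offset_ms else rep(NA_real_, nf)
  samples <- do.call(rbind, lapply(seq_len(n_cycles), function(cc) {
    fr <- ((cc - 1) * cycle_length + 1):(cc * cycle_length)
    w <- fr[which.max(sp[fr])]
    data.frame(t = mean(series$frame_times[fr]), v = sp[w],
               frame = w, offset_ms = offs[w])
  }))
  structure(list(samples = samples, normalization = "raw"),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  s <- x$samples
  cat(sprintf("Recovery curve: %d samples over %.0f s (%s), v %.2f .. %.2f cm/s\n",
              nrow(s), max(s$t) - min(s$t), x$normalization,
              min(s$v), max(s$v)))
  invisible(x)
}

#' Normalise a recovery curve to its end-recovery velocity
#'
#' Divides all velocities by the mean of the final 10% of samples.
#'
#' @param curve A `recovery_curve` with at least 5 samples.
#'
#' @return The curve with `normalization = "end_normalized"`.  Idempotent
#'   up to floating precision.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "recovery_curve"))
  s <- curve$samples
  if (nrow(s) < 5L) stop("need >= 5 samples to normalise")
  n_tail <- max(1L, ceiling(0.1 * nrow(s)))
  end_mean <- mean(utils::tail(s$v, n_tail))
  if (end_mean <= 0) stop("non-positive end-recovery velocity")
  curve$samples$v <- s$v / end_mean
  curve$normalization <- "end_normalized"
  curve
}

# Closed-form time at which the Gompertz curve reaches a given level:
# a*exp(-b*exp(-c*T)) - d = level  =>  T = -log(log(a/(level+d))/b)/c
gompertz_time_at <- function(level, a, b, c, d, x0 = 0) {
  arg <- (level + d) / a
  if (arg <= 0 || arg >= 1)
    stop("target level outside the curve range")
  x0 - log(log(1 / arg) / b) / c
}

#' Fit the modified Gompertz recovery model
#'
#' Nonlinear least squares of `y(x) = a*exp(-b*exp(-c*(x - x0))) - d` to a
#' recovery curve.  The model is linear in `(a, d)` once `(b, c)` are
#' fixed, so the fit uses variable projection: `(b, c)` (and optionally
#' `x0`) are optimised by Nelder-Mead with BFGS polishing while `(a, d)`
#' are solved exactly by linear least squares at every step.
#' Initialisation follows the amplitude/time-range heuristics (`a` from
#' the plateau, `d` from any negative dip, `c` from the time range, `b`
#' from the first sample) plus seeded jittered restarts.  The optional
#' time-shift `x0` is off by default, giving the four-parameter form.
#'
#' @param curve A `recovery_curve` (or data frame with `t` and `v`) with
#'   at least 8 samples spanning rise and plateau.
#' @param fit_x0 Also fit a time shift `x0` (default FALSE).
#' @param n_restarts Number of jittered restarts after the deterministic
#'   start (default 5).
#' @param seed Seed for the restart jitter (default 1).
#'
#' @return An object of class `gompertz_fit`: parameters `a`, `b`, `c`,
#'   `d` (and `x0` if fitted), `t_half_max` (s, plateau-half definition),
#'   `adjusted_r2`, `r2`, `residual_sd`, `n`, `converged`, and `fitted`
#'   (function of time).  Non-convergence across all starts returns
#'   `converged = FALSE` with `NA` parameters.
#' @export
fit_gompertz <- function(curve, fit_x0 = FALSE, n_restarts = 5, seed = 1L) {
  s <- if (inherits(curve, "recovery_curve")) curve$samples else curve
  stopifnot(is.data.frame(s), all(c("t", "v") %in% names(s)))
  x <- s$t; y <- s$v
  n <- length(x)
  if (n < 8L) stop("need >= 8 samples to fit the recovery model")

  fail <- function() structure(
    list(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
         x0 = if (fit_x0) NA_real_ else NULL,
         t_half_max = NA_real_, adjusted_r2 = NA_real_, r2 = NA_real_,
         residual_sd = NA_real_, n = n, converged = FALSE, fitted = NULL),
    class = "gompertz_fit")

  if (stats::sd(y) == 0) {
    f <- fail(); f$degenerate <- TRUE
    warning("constant curve: growth rate unidentifiable")
    return(f)
  }

  # profile RSS over the nonlinear parameters; theta = (log b, log c[, x0])
  lin_solve <- function(theta) {
    b <- exp(theta[1]); c <- exp(theta[2])
    x0 <- if (fit_x0) theta[3] else 0
    E <- exp(-b * exp(-c * (x - x0)))
    X <- cbind(E, -1)
    cf <- tryCatch(qr.coef(qr(X), y), error = function(e) c(NA, NA))
    if (anyNA(cf)) return(list(rss = Inf))
    r <- y - X %*% cf
    list(rss = sum(r^2), a = unname(cf[1]), d = unname(cf[2]),
         b = b, c = c, x0 = x0)
  }
  obj <- function(theta) lin_solve(theta)$rss

  a0 <- max(y)
  d0 <- max(0, -min(y)) + 1e-6
  c0 <- 2 / diff(range(x))
  arg <- (y[1] + d0) / a0
  b0 <- if (arg > 0 && arg < 1) log(1 / arg) * exp(c0 * x[1]) else 3
  starts <- list(c(log(b0), log(c0)))
  jit <- with_seed(seed, lapply(seq_len(n_restarts), function(i)
    stats::runif(2, -1.2, 1.2)))
  for (j in jit) starts[[length(starts) + 1]] <- starts[[1]] + j
  if (fit_x0) starts <- lapply(starts, function(st) c(st, 0))

  best <- NULL
  for (st in starts) {
    o <- tryCatch({
      o1 <- stats::optim(st, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 3000))
      stats::optim(o1$par, obj, method = "BFGS",
                   control = list(reltol = 1e-14, maxit = 500))
    }, error = function(e) NULL)
    if (!is.null(o) && is.finite(o$value) &&
        (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) return(fail())
  sol <- lin_solve(best$par)
  if (!is.finite(sol$rss) || sol$a <= 0) return(fail())

  p <- if (fit_x0) 5L else 4L
  rss <- sol$rss
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  thm <- tryCatch(
    half_max_time_closed(sol$a, sol$b, sol$c, sol$d, x0 = sol$x0,
                         definition = "plateau_half"),
    error = function(e) NA_real_)
  structure(list(
    a = sol$a, b = sol$b, c = sol$c, d = sol$d,
    x0 = if (fit_x0) sol$x0 else NULL,
    t_half_max = thm, adjusted_r2 = adj, r2 = r2,
    residual_sd = sqrt(rss / max(1, n - p)), n = n, converged = TRUE,
    fitted = function(t) gompertz_value(t, sol$a, sol$b, sol$c, sol$d,
                                        sol$x0)),
    class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Gompertz fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Gompertz fit: a = %.3g cm/s, b = %.3g, c = %.3g /s, d = %.3g cm/s\n",
    x$a, x$b, x$c, x$d))
  cat(sprintf("  T_half-max = %.1f s, adjusted R^2 = %.3f (n = %d)\n",
              x$t_half_max, x$adjusted_r2, x$n))
  invisible(x)
}

half_max_time_closed <- function(a, b, c, d, x0 = 0,
                                 definition = c("plateau_half",
                                                "range_half")) {
  definition <- match.arg(definition)
  stopifnot(a > 0, b > 0, c > 0)
  if (definition == "plateau_half") {
    # y(T) = (a - d)/2, half the asymptotic plateau
    if (!((a + d) / (2 * a) > 0 && (a + d) / (2 * a) < 1))
      stop("plateau_half undefined: require 0 < (a+d)/(2a) < 1")
    level <- (a - d) / 2
  } else {
    y0 <- a * exp(-b) - d   # curve value at x = x0
    level <- (y0 + (a - d)) / 2
  }
  gompertz_time_at(level, a, b, c, d, x0)
}

#' Time to half-maximum of a fitted recovery curve
#'
#' `plateau_half` (default) solves `y(T) = (a - d)/2`, half the asymptotic
#' plateau, appropriate when post-fatigue velocity starts near zero:
#' `T = x0 - log(log(2a/(a+d))/b)/c`.  `range_half` solves for the midpoint
#' between `y(0)` and the plateau.
#'
#' @param fit A `gompertz_fit` (or list with `a`, `b`, `c`, `d`, optional
#'   `x0`).
#' @param definition `"plateau_half"` or `"range_half"`.
#'
#' @return Time to half-maximum (s).
#' @export
half_max_time <- function(fit, definition = c("plateau_half", "range_half")) {
  definition <- match.arg(definition)
  x0 <- if (!is.null(fit$x0)) fit$x0 else 0
  half_max_time_closed(fit$a, fit$b, fit$c, fit$d, x0, definition)
}

#' Mono-exponential phosphocreatine recovery fit
#'
#' Least-squares fit of `y(t) = y_end - dPCr * exp(-kPCr * t)` to a table
#' of post-exercise phosphocreatine areas, giving the recovery rate kPCr
#' and its half time `log(2)/kPCr`.
#'
#' @param time Sample times (s since end of exercise).
#' @param pcr Phosphocreatine areas (arbitrary units).
#'
#' @return An object of class `monoexp_fit`: `k_pcr` (1/s), `y_end`,
#'   `delta_pcr`, `half_time` (s), `r2`, `converged`, and `recovering`
#'   (FALSE, with `NA` rate, when the series does not rise).
#' @export
fit_monoexponential <- function(time, pcr) {
  stopifnot(length(time) == length(pcr))
  n <- length(time)
  if (n < 6L) stop("need >= 6 samples")
  if (stats::cor(time, pcr) <= 0) {
    warning("series does not recover (non-positive trend)")
    return(structure(list(k_pcr = NA_real_, y_end = NA_real_,
                          delta_pcr = NA_real_, half_time = NA_real_,
                          r2 = NA_real_, converged = FALSE,
                          recovering = FALSE),
                     class = "monoexp_fit"))
  }
  y_end0 <- max(pcr)
  delta0 <- max(y_end0 - pcr[1], 1e-6)
  # crude rate from the log-linear tail-corrected residual
  pos <- (y_end0 + 0.05 * delta0) - pcr
  k0 <- tryCatch({
    sl <- stats::coef(stats::lm(log(pos) ~ time))[2]
    max(1e-5, -unname(sl))
  }, error = function(e) 1 / diff(range(time)))
  fit <- tryCatch(
    stats::nls(pcr ~ y_end - delta * exp(-k * time),
               start = list(y_end = y_end0, delta = delta0, k = k0),
               algorithm = "port",
               lower = c(y_end = -Inf, delta = 1e-12, k = 1e-9),
               control = stats::nls.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(k_pcr = NA_real_, y_end = NA_real_,
                          delta_pcr = NA_real_, half_time = NA_real_,
                          r2 = NA_real_, converged = FALSE,
                          recovering = TRUE),
                     class = "monoexp_fit"))
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((pcr - mean(pcr))^2)
  structure(list(k_pcr = unname(cf["k"]), y_end = unname(cf["y_end"]),
                 delta_pcr = unname(cf["delta"]),
                 half_time = log(2) / unname(cf["k"]),
                 r2 = 1 - rss / tss, converged = TRUE, recovering = TRUE),
            class = "monoexp_fit")
}

#' @export
print.monoexp_fit <- function(x, ...) {
  if (!x$converged) cat("Mono-exponential fit: not converged\n")
  else cat(sprintf(
    "PCr recovery: kPCr = %.4g /s, half time = %.1f s, R^2 = %.3f\n",
    x$k_pcr, x$half_time, x$r2))
  invisible(x)
}
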