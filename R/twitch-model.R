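# Analytic twitch tension model used by the phantom generator.
#
# Tension follows a gamma-shaped impulse response
#   F(t) = A * u^k * exp(-u),  u = (t - t0) / tau,  t > t0  (0 before onset)
# whose velocity v = dF/dt changes sign exactly once after onset (at the
# tension peak t = t0 + k*tau) and whose speed |v| has two interior maxima at
# t = t0 + tau*(k -/+ sqrt(k)).  Those closed forms are the landmark oracle
# for the whole pipeline: the first |v| maximum plays the role of the first
# signal minimum of a motion-sensitised series, the tension peak the return
# to baseline, and the second |v| maximum the second signal minimum.

#' Twitch kinetics parameters
#'
#' Parameter set for the gamma-shaped twitch tension model used by the
#' phantom generator.
#'
#' @param t0 Onset delay between stimulus and tension onset (ms).
#' @param k Dimensionless shape parameter; must be >= 2 so that the speed
#'   profile has two interior maxima (the biphasic signal dip).
#' @param tau Timescale of the twitch (ms), > 0.
#' @param A Peak-scaling tension amplitude (arbitrary units), > 0.
#' @param beta Signal attenuation coefficient (s/cm): sensitivity of the
#'   motion-encoded magnitude signal to fibre speed, >= 0.
#' @param S0 Baseline (unstimulated) signal level, > 0.
#'
#' @return An object of class `twitch_kinetics_params`.
#' @export
twitch_kinetics_params <- function(t0 = 10, k = 2.3, tau = 50, A = 1,
                                   beta = 0.35, S0 = 100) {
  stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0))
  if (!(is.numeric(k) && length(k) == 1L && k >= 2))
    stop("shape `k` must be a single number >= 2")
  if (!(is.numeric(tau) && length(tau) == 1L && tau > 0))
    stop("timescale `tau` must be > 0")
  if (!(is.numeric(A) && length(A) == 1L && A >= 0))
    stop("amplitude `A` must be >= 0")
  if (!(is.numeric(beta) && length(beta) == 1L && beta >= 0))
    stop("`beta` must be >= 0")
  if (!(is.numeric(S0) && length(S0) == 1L && S0 > 0))
    stop("baseline `S0` must be > 0")
  structure(list(t0 = t0, k = k, tau = tau, A = A, beta = beta, S0 = S0),
            class = "twitch_kinetics_params")
}

#' @export
print.twitch_kinetics_params <- function(x, ...) {
  cat(sprintf(
    "Twitch kinetics: t0 = %g ms, k = %g, tau = %g ms, A = %g, beta = %g s/cm, S0 = %g\n",
    x$t0, x$k, x$tau, x$A, x$beta, x$S0))
  invisible(x)
}

# Tension F(t) in arbitrary units; vectorised over t (ms).
twitch_tension <- function(t, params) {
  u <- (t - params$t0) / params$tau
  f <- numeric(length(t))
  pos <- u > 0
  f[pos] <- params$A * u[pos]^params$k * exp(-u[pos])
  f
}

# Velocity dF/dt in tension-units per ms.
twitch_velocity <- function(t, params) {
  u <- (t - params$t0) / params$tau
  v <- numeric(length(t))
  pos <- u > 0
  v[pos] <- (params$A / params$tau) * exp(-u[pos]) *
    u[pos]^(params$k - 1) * (params$k - u[pos])
  v
}

# Scale the tension amplitude so that the motion-encoded signal at the
# first speed maximum is attenuated by exp(-target_attenuation), i.e. the
# first dip bottoms out at S0 * exp(-target_attenuation).  The default 0.8
# puts the dip floor at ~45% of baseline, the deep biphasic dips seen in
# stimulated muscle at working current.
calibrate_twitch_amplitude <- function(params, target_attenuation = 0.8) {
  if (params$beta <= 0) return(params)
  unit <- params
  unit$A <- 1
  v1 <- abs(twitch_velocity(params$t0 + params$tau *
                              (params$k - sqrt(params$k)), unit))
  params$A <- target_attenuation / (params$beta * v1)
  params
}

# Closed-form landmark times (ms since stimulus).  t_start is the tension
# onset, t_min1/t_min2 the two speed maxima, t_middle the tension peak where
# velocity crosses zero and the motion-encoded signal returns to baseline.
twitch_landmark_truth <- function(params) {
  with(params, list(
    t_start  = t0,
    t_min1   = t0 + tau * (k - sqrt(k)),
    t_middle = t0 + tau * k,
    t_min2   = t0 + tau * (k + sqrt(k)),
    t_rise       = tau * (k - sqrt(k)),
    t_contract   = tau * k,
    t_half_relax = 2 * tau * sqrt(k)
  ))
}

#' Simulate a single twitch tension/velocity trace
#'
#' Evaluates the gamma-shaped tension model and its time derivative on a
#' supplied time axis and returns the closed-form landmark times.
#'
#' @param params A [twitch_kinetics_params()] object.
#' @param time_axis Ordered vector of times since stimulus (ms).  Must extend
#'   beyond the second speed maximum (`t0 + (k + sqrt(k)) * tau`) so the full
#'   biphasic response is contained.
#'
#' @return A list with `time` (the axis), `tension`, `velocity`, and
#'   `landmarks` (closed-form times; all `NA` with `defined = FALSE` when
#'   the amplitude is zero).
#' @export
#' @examples
#' p <- twitch_kinetics_params(t0 = 0, k = 2, tau = 50)
#' tr <- simulate_twitch_kinetics(p, seq(-45, 400, by = 5))
#' tr$landmarks$t_min1   # 50 * (2 - sqrt(2)) = 29.29 ms
simulate_twitch_kinetics <- function(params, time_axis) {
  stopifnot(inherits(params, "twitch_kinetics_params"),
            is.numeric(time_axis), length(time_axis) >= 2L)
  if (is.unsorted(time_axis, strictly = TRUE))
    stop("`time_axis` must be strictly increasing")
  t_second <- params$t0 + (params$k + sqrt(params$k)) * params$tau
  if (params$A > 0 && max(time_axis) < t_second)
    stop(sprintf(
      "time axis too short: must reach %.1f ms to contain the second speed maximum",
      t_second))
  tension  <- twitch_tension(time_axis, params)
  velocity <- twitch_velocity(time_axis, params)
  if (params$A == 0) {
    lm <- list(t_start = NA_real_, t_min1 = NA_real_, t_middle = NA_real_,
               t_min2 = NA_real_, t_rise = NA_real_, t_contract = NA_real_,
               t_half_relax = NA_real_, defined = FALSE)
  } else {
    lm <- c(twitch_landmark_truth(params), defined = TRUE)
  }
  list(time = time_axis, tension = tension, velocity = velocity,
       landmarks = lm)
}
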