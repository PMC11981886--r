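# Study-level summaries: test-retest repeatability and group comparisons.

#' Test-retest repeatability
#'
#' Per subject the absolute percentage difference between two scans,
#' `100 * |s1 - s2| / pair mean` (symmetric denominator; the scan-1
#' denominator is selectable), and its mean over subjects.
#'
#' @param scan1,scan2 Paired per-subject metric values, equal length.
#' @param metric Metric name carried through to the result.
#' @param denominator `"pair_mean"` (default, symmetric) or `"scan1"`.
#'
#' @return An object of class `repeatability_result`: `per_subject` (%),
#'   `mean_pct_diff` (%), `metric`, `n_subjects`.  Pairs with a zero
#'   denominator are excluded with a warning.
#' @export
repeatability <- function(scan1, scan2, metric = "metric",
                          denominator = c("pair_mean", "scan1")) {
  denominator <- match.arg(denominator)
  stopifnot(length(scan1) == length(scan2), length(scan1) >= 1L)
  den <- switch(denominator,
                pair_mean = (scan1 + scan2) / 2,
                scan1 = scan1)
  bad <- den == 0
  if (any(bad)) {
    warning(sprintf("excluding %d pair(s) with zero denominator", sum(bad)))
    scan1 <- scan1[!bad]; scan2 <- scan2[!bad]; den <- den[!bad]
  }
  if (!length(den)) stop("no usable pairs")
  per <- 100 * abs(scan1 - scan2) / den
  structure(list(per_subject = per, mean_pct_diff = mean(per),
                 metric = metric, n_subjects = length(per)),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Repeatability (%s): mean %% difference = %.1f%% (n = %d)\n",
              x$metric, x$mean_pct_diff, x$n_subjects))
  invisible(x)
}

#' Compare two groups with a Student's t-test
#'
#' Two-sided parametric t-test, paired or unpaired (pooled variance for
#' the unpaired case, the classical Student form).
#'
#' @param a,b Numeric vectors (equal length when `paired`).
#' @param paired Paired test (default FALSE).
#'
#' @return An object of class `comparison_result`: group means and SDs,
#'   `t`, `df`, `p`, `paired`, and a `degenerate` flag when the test
#'   statistic is undefined (zero variance).
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  if (paired && length(a) != length(b))
    stop("paired comparison needs equal lengths")
  degenerate <- if (paired) stats::sd(a - b) == 0 && any(a != b)
                else stats::sd(a) == 0 && stats::sd(b) == 0
  if (paired && stats::sd(a - b) == 0 && all(a == b)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(a) - 1),
               p.value = 1)
  } else if (degenerate) {
    warning("zero variance: test statistic undefined")
    tt <- list(statistic = c(t = NA_real_),
               parameter = c(df = NA_real_), p.value = NA_real_)
  } else {
    tt <- stats::t.test(a, b, paired = paired, var.equal = !paired)
  }
  structure(list(mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, paired = paired,
                 degenerate = degenerate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s t-test: %.1f +/- %.1f vs %.1f +/- %.1f, t = %.3f, p = %.3g\n",
              if (x$paired) "Paired" else "Unpaired",
              x$mean_a, x$sd_a, x$mean_b, x$sd_b, x$t, x$p))
  invisible(x)
}
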