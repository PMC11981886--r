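# Core containers: a 2D+frame dynamic image series and a binary muscle mask.

#' Dynamic image series
#'
#' A stack of congruent 2D frames over an ordered frame axis.  The axis
#' carries either a stimulus-to-readout latency in milliseconds (latency
#' scans, one stimulus per frame) or a wall-clock time in seconds (cyclic
#' recovery scans).  The convention for latency scans is "time since
#' stimulus at slice readout": frames whose stimulus fires after readout
#' carry negative latency and constitute the unstimulated baseline.
#'
#' @param data Numeric array `rows x cols x frames`.
#' @param frame_times Numeric vector, one entry per frame: latency (ms) or
#'   wall time (s) depending on `time_unit`.
#' @param time_unit `"ms"` (stimulus latency) or `"s"` (wall clock).
#' @param modality One of `"pgse_magnitude"`, `"pc_velocity"`, `"pc_phase"`.
#' @param venc Velocity encoding (cm/s); required iff `modality` is
#'   `"pc_phase"`.
#' @param pixel_spacing In-plane pixel size (mm), length 1 or 2.
#' @param frame_meta Optional data frame of per-frame metadata (cycle index,
#'   latency offset, ...) with one row per frame.
#'
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, frame_times,
                           time_unit = c("ms", "s"),
                           modality = c("pgse_magnitude", "pc_velocity",
                                        "pc_phase"),
                           venc = NULL, pixel_spacing = c(1.5, 1.5),
                           frame_meta = NULL) {
  time_unit <- match.arg(time_unit)
  modality <- match.arg(modality)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n_frames <- dim(data)[3]
  if (length(frame_times) != n_frames)
    stop(sprintf("frame axis length (%d) != number of frames (%d)",
                 length(frame_times), n_frames))
  if (time_unit == "ms" && is.unsorted(frame_times, strictly = TRUE))
    stop("latency axis must be strictly increasing for latency scans")
  if (modality == "pc_phase") {
    if (is.null(venc) || !is.numeric(venc) || venc <= 0)
      stop("`venc` (cm/s, > 0) is required for phase-contrast phase data")
  }
  if (!is.null(frame_meta)) {
    stopifnot(is.data.frame(frame_meta), nrow(frame_meta) == n_frames)
  }
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  structure(list(data = data,
                 frame_times = as.numeric(frame_times),
                 time_unit = time_unit,
                 modality = modality,
                 venc = venc,
                 pixel_spacing = pixel_spacing,
                 frame_meta = frame_meta),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Dynamic series: %d x %d pixels, %d frames (%s, %s)\n",
              d[1], d[2], d[3], x$modality, x$time_unit))
  cat(sprintf("  frame axis: %g .. %g %s\n",
              min(x$frame_times), max(x$frame_times), x$time_unit))
  if (!is.null(x$venc)) cat(sprintf("  VENC: %g cm/s\n", x$venc))
  invisible(x)
}

#' @export
dim.dynamic_series <- function(x) dim(x$data)

n_frames <- function(series) dim(series$data)[3]

#' Binary muscle mask
#'
#' @param mask Logical or 0/1 numeric matrix, congruent with the in-plane
#'   grid of the series it will be applied to.
#' @param label Muscle name (default `"TA"`, tibialis anterior).
#'
#' @return An object of class `muscle_mask`.
#' @export
muscle_mask <- function(mask, label = "TA") {
  if (is.numeric(mask)) mask <- mask != 0
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("mask contains no in-mask voxel")
  structure(list(mask = mask, label = label), class = "muscle_mask")
}

#' @export
print.muscle_mask <- function(x, ...) {
  cat(sprintf("Muscle mask '%s': %d / %d voxels in mask\n",
              x$label, sum(x$mask), length(x$mask)))
  invisible(x)
}

# Check a mask is geometrically congruent with a series (same grid);
# masks are never resampled.
check_mask_congruent <- function(series, mask) {
  stopifnot(inherits(series, "dynamic_series"), inherits(mask, "muscle_mask"))
  if (!identical(dim(mask$mask), dim(series$data)[1:2]))
    stop(sprintf("mask grid (%s) does not match series grid (%s)",
                 paste(dim(mask$mask), collapse = "x"),
                 paste(dim(series$data)[1:2], collapse = "x")))
  invisible(TRUE)
}

# Per-frame summary of |values| over the mask: "mean" (default) or "median".
frame_mask_summary <- function(series, mask, stat = c("mean", "median"),
                               absolute = TRUE) {
  stat <- match.arg(stat)
  check_mask_congruent(series, mask)
  idx <- which(mask$mask)
  fun <- if (stat == "mean") mean else stats::median
  vapply(seq_len(n_frames(series)), function(f) {
    v <- series$data[, , f][idx]
    if (absolute) v <- abs(v)
    fun(v)
  }, numeric(1))
}
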