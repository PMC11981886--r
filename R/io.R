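# Readers/writers binding the pipeline to files: NIfTI volumes with CSV
# frame sidecars, masks, result tables, and run manifests.

#' Read a dynamic series from a NIfTI volume and CSV sidecar
#'
#' The volume is stored as `rows x cols x frames`; the sidecar carries one
#' row per frame with a `frame` column plus either `latency_ms` (latency
#' scans) or `time_s` (wall-clock scans), and optionally `cycle` and
#' `latency_offset_ms` for cyclic scans or `current_mA` for setup ramps.
#'
#' @param nifti_path Path to the `.nii` series.
#' @param sidecar_path Path to the frame-axis CSV.
#' @param modality Series modality (see [dynamic_series()]).
#' @param venc Velocity encoding (cm/s), required for `pc_phase`.
#'
#' @return A [dynamic_series()].
#' @export
read_series <- function(nifti_path, sidecar_path,
                        modality = c("pgse_magnitude", "pc_velocity",
                                     "pc_phase"),
                        venc = NULL) {
  modality <- match.arg(modality)
  vol <- read_nifti(nifti_path)
  sc <- utils::read.csv(sidecar_path)
  nf <- dim(vol$data)[3]
  if (nrow(sc) != nf)
    stop(sprintf("frame count mismatch: volume has %d frames, sidecar %d rows",
                 nf, nrow(sc)))
  if ("latency_ms" %in% names(sc)) {
    times <- sc$latency_ms; unit <- "ms"
  } else if ("time_s" %in% names(sc)) {
    times <- sc$time_s; unit <- "s"
  } else stop("sidecar needs a latency_ms or time_s column")
  dynamic_series(vol$data, times, time_unit = unit, modality = modality,
                 venc = venc, pixel_spacing = vol$pixdim[1:2],
                 frame_meta = sc)
}

#' Write a dynamic series to NIfTI + CSV sidecar
#'
#' @param series A [dynamic_series()].
#' @param nifti_path,sidecar_path Output paths.
#'
#' @return Invisibly, the two paths.
#' @export
write_series <- function(series, nifti_path, sidecar_path) {
  stopifnot(inherits(series, "dynamic_series"))
  write_nifti(series$data, nifti_path,
              pixdim = c(series$pixel_spacing, 1),
              descrip = series$modality)
  sc <- if (!is.null(series$frame_meta)) series$frame_meta
        else data.frame(frame = seq_len(n_frames(series)))
  tcol <- if (series$time_unit == "ms") "latency_ms" else "time_s"
  if (!tcol %in% names(sc)) sc[[tcol]] <- series$frame_times
  utils::write.csv(sc, sidecar_path, row.names = FALSE)
  invisible(c(nifti_path, sidecar_path))
}

#' Read a binary mask from NIfTI
#'
#' @param path Path to the mask volume (any non-zero voxel is in-mask).
#' @param label Muscle label.
#' @return A [muscle_mask()].
#' @export
read_mask <- function(path, label = "TA") {
  vol <- read_nifti(path)
  m <- vol$data
  if (length(dim(m)) == 3L) m <- m[, , 1]
  muscle_mask(m != 0, label = label)
}

#' Write a binary mask to NIfTI
#'
#' @param mask A [muscle_mask()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "muscle_mask"))
  write_nifti(array(as.numeric(mask$mask), dim = c(dim(mask$mask), 1L)),
              path, datatype = 2L, descrip = paste0("mask:", mask$label))
  invisible(path)
}

#' Write pipeline outputs with a run manifest
#'
#' Writes parametric maps (NIfTI), the category map, CSV summaries and
#' histogram tables, fit records (JSON) and a manifest recording the
#' effective configuration and seed.  A `.incomplete` marker file guards
#' against partial writes: it is created first and removed last, so its
#' presence signals an interrupted run.
#'
#' @param results Named list; recognised entries: `maps` (a
#'   `metric_map_set`), `category` (a `category_map`), `histograms`
#'   (named list of `histogram_summary`), `gompertz` (a `gompertz_fit`),
#'   `recovery` (a `recovery_curve`), `config` (list echoed into the
#'   manifest).
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#'
#' @return Invisibly, the manifest (list with `files` and `config`).
#' @export
write_outputs <- function(results, out_dir, seed = NA_integer_) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 warning = function(w) FALSE)
  if (!isTRUE(ok) || !file.exists(probe))
    stop("output directory is not writable: ", out_dir)
  unlink(probe)
  marker <- file.path(out_dir, ".incomplete")
  file.create(marker)
  files <- character(0)
  add <- function(f) files <<- c(files, basename(f))

  if (!is.null(results$maps)) {
    for (m in c("t_rise", "t_contract", "t_half_relax")) {
      p <- file.path(out_dir, paste0(m, ".nii"))
      write_nifti(results$maps[[m]]$values, p, descrip = m)
      add(p)
    }
    summ <- do.call(rbind, lapply(c("t_rise", "t_contract", "t_half_relax"),
      function(m) {
        mm <- results$maps[[m]]
        data.frame(metric = m, mean_ms = mm$mean, sd_ms = mm$sd,
                   n_valid = mm$n_valid,
                   excluded_fraction = results$maps$excluded_fraction)
      }))
    p <- file.path(out_dir, "metric_summary.csv")
    utils::write.csv(summ, p, row.names = FALSE); add(p)
  }
  if (!is.null(results$category)) {
    p <- file.path(out_dir, "category_map.nii")
    cm <- results$category$classes
    cm[is.na(cm)] <- 0L
    write_nifti(array(cm, dim = c(dim(cm), 1L)), p, datatype = 8L,
                descrip = "category")
    add(p)
  }
  if (!is.null(results$histograms)) {
    for (nm in names(results$histograms)) {
      h <- results$histograms[[nm]]
      p <- file.path(out_dir, paste0("histogram_", nm, ".csv"))
      utils::write.csv(
        data.frame(bin_left = utils::head(h$breaks, -1),
                   bin_right = utils::tail(h$breaks, -1),
                   count = h$counts),
        p, row.names = FALSE)
      add(p)
    }
  }
  if (!is.null(results$recovery)) {
    p <- file.path(out_dir, "recovery_curve.csv")
    utils::write.csv(results$recovery$samples, p, row.names = FALSE); add(p)
  }
  if (!is.null(results$gompertz)) {
    g <- results$gompertz
    p <- file.path(out_dir, "gompertz_fit.json")
    jsonlite::write_json(
      list(a = g$a, b = g$b, c = g$c, d = g$d,
           t_half_max_s = g$t_half_max, adjusted_r2 = g$adjusted_r2,
           r2 = g$r2, n = g$n, converged = g$converged),
      p, auto_unbox = TRUE, digits = NA)
    add(p)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("mumri")),
                   r_version = as.character(getRversion()),
                   seed = seed,
                   config = results$config,
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(marker)
  invisible(manifest)
}

#' Read a run configuration from YAML
#'
#' Validates stage parameters against their documented ranges before any
#' stage runs and fills defaults for absent entries.
#'
#' @param path Path to a YAML file; `NULL` gives pure defaults.
#'
#' @return A validated named list of parameters.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(smoothing_window = 3, target_step_ms = 0.5,
                   onset_multiplier = 3, fraction = 0.67,
                   cycle_length = 5, bins = 50,
                   category_mode = "fixed_edges",
                   category_edges = c(100, 150, 200),
                   half_max_definition = "plateau_half",
                   rng_seed = 1L)
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  with(cfg, {
    stopifnot(smoothing_window >= 1, target_step_ms > 0,
              onset_multiplier > 0, fraction > 0, fraction <= 1,
              cycle_length >= 1, bins >= 2,
              category_mode %in% c("fixed_edges", "equal_span"),
              length(category_edges) == 3,
              half_max_definition %in% c("plateau_half", "range_half"))
  })
  cfg
}
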