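## Protocol configuration: a single JSON-serializable record holding the
## trajectory geometry, reconstruction settings and noise/seed block, with
## strict schema validation (unknown keys are rejected) and physical
## consistency checks.

config_defaults <- function() {
  list(
    scheme = "dw_concept", matrix = 64L, fov_m = 0.22,
    tr_s = 0.6, acq_delay_s = 1.3e-3, adc_dwell_s = 4e-6,
    n_interleaves = 3L, n_fid_points = 819L,
    samples_per_rev = NULL, n_circles = NULL,
    gmax_mT_m = 40, smax_mT_m_ms = 200,
    kernel_width = 3L, overgrid = 2, dcf_max_iter = 50L, dcf_tol = 5e-3,
    deapodize = TRUE, post_correct = TRUE,
    noise_sd = 0, seed = 1L,
    phantom = "single_disk", n_replicas = 256L
  )
}

#' Load and validate a protocol configuration
#'
#' Reads a JSON protocol file, fills defaults, rejects unknown keys, and
#' checks physical consistency: the revolution time must be an integer
#' number of ADC dwells, the outermost circle must be reachable within the
#' gradient limits, and the revolution frequency must clear the forbidden
#' acoustic bands.  The shipped default (`path = NULL`) is the published
#' 7 T protocol: TR 600 ms, acquisition delay 1.3 ms, matrix 64, FOV
#' 220 mm, 3 temporal interleaves, 819 FID points.
#'
#' @param path JSON file path, or NULL for the default configuration.
#' @return A validated list of class `protocol_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, user, keep.null = TRUE)
  }
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg A configuration list.
#' @export
validate_config <- function(cfg) {
  spec <- trajectory_spec(
    scheme = cfg$scheme, matrix = cfg$matrix, fov = cfg$fov_m,
    n_circles = cfg$n_circles, n_interleaves = cfg$n_interleaves,
    n_fid_points = cfg$n_fid_points, adc_dwell = cfg$adc_dwell_s,
    samples_per_rev = cfg$samples_per_rev,
    tr = cfg$tr_s, acq_delay = cfg$acq_delay_s)
  if (abs(spec$samples_per_rev * spec$adc_dwell - spec$t_rev) > 1e-12)
    stopf("inconsistent timing: samples_per_rev * adc_dwell != t_rev")
  limits <- gradient_limits(cfg$gmax_mT_m, cfg$smax_mT_m_ms)
  ## gradient feasibility of the outermost (hardest) circle
  design_circle_waveform(max(spec$radii), spec$t_rev, spec$adc_dwell, limits)
  ac <- validate_acoustics(spec$t_rev, spec$n_interleaves, limits)
  if (!ac$pass)
    warning(sprintf(
      "revolution frequency %.0f Hz lies in a forbidden acoustic band [%g, %g]",
      ac$fundamental_hz, ac$offending_band[1], ac$offending_band[2]),
      call. = FALSE)
  cfg$samples_per_rev <- spec$samples_per_rev
  cfg$n_circles <- spec$n_circles
  structure(cfg, class = "protocol_config", spec = spec)
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Run one pipeline stage and write its artifacts
#'
#' Executes a `design`, `simulate`, `recon`, `psf`, `snr-theory` or
#' `experiment` stage for a validated configuration, writes its outputs
#' under `out_dir`, and returns (and writes) a machine-readable JSON
#' report with seeds, metrics and runtimes.  Errors in any stage
#' propagate with stage-tagged context and leave no partial report.
#'
#' @param command Stage name.
#' @param cfg A `protocol_config` (see [load_config()]).
#' @param out_dir Output directory (created if missing).
#' @param experiment For `command = "experiment"`: `"snr-ratios"` or
#'   `"localization"`.
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(command = c("design", "simulate", "recon", "psf",
                                     "snr-theory", "experiment"),
                         cfg = load_config(), out_dir = ".",
                         experiment = c("snr-ratios", "localization")) {
  command <- match.arg(command)
  stopifnot(inherits(cfg, "protocol_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- attr(cfg, "spec")
  t0 <- Sys.time()
  report <- list(command = command, seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("dwconcept")))
  res <- tryCatch(switch(command,
    design = {
      path <- file.path(out_dir, "trajectory.csv")
      write_trajectory(spec, path,
                       gradient_limits(cfg$gmax_mT_m, cfg$smax_mT_m_ms))
      list(trajectory = path, n_circles = spec$n_circles,
           nyquist_min = nyquist_min_circles(cfg$scheme, cfg$matrix, cfg$fov_m),
           scan_time_s = scan_time(spec)$total_s)
    },
    simulate = {
      acq <- acquire(phantom_preset(cfg$phantom, cfg$fov_m), spec,
                     noise_model(cfg$noise_sd, cfg$seed))
      path <- file.path(out_dir, "samples.csv")
      write_sampled_kspace(acq, path)
      list(samples = path, n_samples = nrow(acq$traj), n_fid = acq$n_fid)
    },
    recon = {
      acq <- acquire(phantom_preset(cfg$phantom, cfg$fov_m), spec,
                     noise_model(cfg$noise_sd, cfg$seed))
      img <- reconstruct(acq, deapodize = cfg$deapodize,
                         post_correct = cfg$post_correct,
                         max_iter = cfg$dcf_max_iter, tol = cfg$dcf_tol)
      path <- file.path(out_dir, "image.csv")
      write_spectral_image(img, path)
      list(image = path, matrix = img$matrix)
    },
    psf = {
      p <- psf(spec)
      write.csv(p$profile, file.path(out_dir, "psf_profile.csv"),
                row.names = FALSE)
      list(fwhm_voxels = p$fwhm_voxels, sidelobe_level = p$sidelobe_level)
    },
    `snr-theory` = as.list(snr_theory_table()),
    experiment = {
      experiment <- match.arg(experiment)
      if (experiment == "snr-ratios") {
        ex <- experiment_snr_ratios(matrix = min(cfg$matrix, 32L),
                                    fov = cfg$fov_m,
                                    noise_sd = max(cfg$noise_sd, 0.02),
                                    n_replicas = cfg$n_replicas,
                                    seed = cfg$seed)
        list(ratios = as.list(ex$ratios), expected = as.list(ex$expected),
             n_replicas = ex$n_replicas, seeds = ex$seeds)
      } else {
        ex <- experiment_localization(matrix = min(cfg$matrix, 32L),
                                      fov = cfg$fov_m)
        list(leakage = as.list(ex$leakage), psf_rms = as.list(ex$psf_rms))
      }
    }),
    error = function(e) stopf("stage '%s' failed: %s", command, conditionMessage(e)))
  report$results <- res
  report$runtime_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(out_dir, paste0(command, "_report.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

#' Export a sampled k-space container to CSV (+ JSON sidecar)
#'
#' Long format: one row per (spatial sample, FID point) with position,
#' timestamp and complex value split into real/imaginary columns.
#'
#' @param samples A [sampled_kspace].
#' @param path CSV path.
#' @export
write_sampled_kspace <- function(samples, path) {
  nf <- samples$n_fid
  tr <- samples$traj
  df <- data.frame(
    kx = rep(tr$kx, nf), ky = rep(tr$ky, nf),
    circle = rep(tr$circle, nf),
    fid = rep(seq_len(nf) - 1L, each = nrow(tr)),
    t_acq = samples$acq_delay + rep(tr$tau, nf) +
      rep(seq_len(nf) - 1L, each = nrow(tr)) * samples$spectral_dwell,
    re = as.vector(Re(samples$data)), im = as.vector(Im(samples$data)))
  write.csv(df, path, row.names = FALSE)
  meta <- list(scheme = samples$scheme, matrix = samples$matrix,
               fov_m = samples$fov, spectral_dwell_s = samples$spectral_dwell,
               acq_delay_s = samples$acq_delay, n_fid = nf)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export a spectral image to CSV (long format)
#'
#' @param image A `spectral_image`.
#' @param path CSV path.
#' @export
write_spectral_image <- function(image, path) {
  m <- image$matrix
  df <- data.frame(
    voxel_x = rep(rep(seq_len(m) - 1L, m), image$n_fid),
    voxel_y = rep(rep(seq_len(m) - 1L, each = m), image$n_fid),
    fid = rep(seq_len(image$n_fid) - 1L, each = m * m),
    re = as.vector(Re(image$data)), im = as.vector(Im(image$data)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
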