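## Forward sampling of a phantom along a trajectory, with true
## per-sample acquisition timestamps and complex Gaussian noise.

#' Complex Gaussian noise model
#'
#' @param sd Standard deviation of each real/imaginary component per
#'   sample (so `E|n|^2 = 2 sd^2`); `sd = 0` means noiseless.
#' @param seed Integer seed; identical seeds give identical realizations.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd = 0, seed = 1L) {
  stopifnot(sd >= 0)
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_model")
}

## Internal constructor for the sampled k-space container.
new_sampled_kspace <- function(traj, data, spectral_dwell, acq_delay,
                               scheme, matrix, fov, extra = list()) {
  structure(c(list(traj = traj, data = data,
                   spectral_dwell = spectral_dwell, acq_delay = acq_delay,
                   n_fid = ncol(data), scheme = scheme,
                   matrix = matrix, fov = fov,
                   phase_corrected = FALSE), extra),
            class = "sampled_kspace")
}

#' @export
print.sampled_kspace <- function(x, ...) {
  cat(sprintf("<sampled_kspace> %s | %d spatial samples x %d FID points (dwell %.3g ms)\n",
              x$scheme, nrow(x$traj), x$n_fid, x$spectral_dwell * 1e3))
  invisible(x)
}

#' Acquire a phantom along a concentric-circle trajectory
#'
#' Evaluates the analytic phantom signal at every sample position and
#' timestamp `t = acq_delay + m * spectral_dwell + tau` (FID index `m`,
#' intra-revolution offset `tau`, per the temporal interleave schedule)
#' and adds i.i.d. complex Gaussian noise.
#'
#' @param phantom An [mrsi_phantom].
#' @param spec A [trajectory_spec].
#' @param noise A [noise_model].
#' @return A [sampled_kspace]: `traj` (per spatial sample: `kx`, `ky`,
#'   `circle`, `azimuth`, `tau`) and `data` (`n_samples x n_fid` complex).
#' @export
acquire <- function(phantom, spec, noise = noise_model()) {
  stopifnot(inherits(phantom, "mrsi_phantom"),
            inherits(spec, "trajectory_spec"),
            inherits(noise, "noise_model"))
  tr <- trajectory_samples(spec)
  dt <- spec$interleaves$spectral_dwell
  nf <- spec$n_fid_points
  t_ref <- spec$acq_delay + (seq_len(nf) - 1) * dt
  data <- matrix(0i, nrow(tr), nf)
  ## the FID factor exp(z (t_ref + tau)) separates per resonance, so each
  ## (shape, resonance) term is a rank-1 outer product
  for (shape in phantom$shapes) {
    spatial <- shape_ktransform(shape, tr$kx, tr$ky)
    for (m in seq_len(nrow(shape$resonances))) {
      r <- shape$resonances[m, ]
      z <- 2i * pi * (r$freq_hz + shape$b0_offset_hz) - 1 / r$t2star_s
      data <- data + r$amplitude *
        outer(spatial * exp(z * tr$tau), exp(z * t_ref))
    }
  }
  if (noise$sd > 0) {
    set.seed(noise$seed)
    n <- length(data)
    data <- data + complex(real = rnorm(n, 0, noise$sd),
                           imaginary = rnorm(n, 0, noise$sd))
  }
  new_sampled_kspace(tr, data, dt, spec$acq_delay, spec$scheme,
                     spec$matrix, spec$fov, list(spec = spec))
}

#' Acquire a phantom with elliptical (circular-footprint) phase encoding
#'
#' The Cartesian gold-standard protocol: one k-space point per excitation,
#' full FID per point, points restricted to the disk `|k| <=
#' k_outer(matrix, fov)`.  Sample timestamps carry no intra-readout offset
#' (`tau = 0`).
#'
#' @inheritParams acquire
#' @param matrix,fov Grid geometry.
#' @param n_fid_points,spectral_dwell,acq_delay Spectral dimension.
#' @return A [sampled_kspace] with extra integer cell columns `ix`, `iy`.
#' @export
acquire_epe <- function(phantom, matrix, fov, n_fid_points, spectral_dwell,
                        acq_delay = 1.3e-3, noise = noise_model()) {
  stopifnot(inherits(phantom, "mrsi_phantom"))
  ko <- k_outer(matrix, fov)
  ix <- rep(seq_len(matrix), times = matrix)
  iy <- rep(seq_len(matrix), each = matrix)
  kx <- (ix - 1 - matrix / 2) / fov
  ky <- (iy - 1 - matrix / 2) / fov
  keep <- sqrt(kx^2 + ky^2) <= ko
  tr <- data.frame(kx = kx[keep], ky = ky[keep], circle = NA_integer_,
                   azimuth = NA_integer_, tau = 0,
                   ix = ix[keep], iy = iy[keep])
  t_ref <- acq_delay + (seq_len(n_fid_points) - 1) * spectral_dwell
  data <- matrix(0i, nrow(tr), n_fid_points)
  for (shape in phantom$shapes) {
    spatial <- shape_ktransform(shape, tr$kx, tr$ky)
    for (m in seq_len(nrow(shape$resonances))) {
      r <- shape$resonances[m, ]
      z <- 2i * pi * (r$freq_hz + shape$b0_offset_hz) - 1 / r$t2star_s
      data <- data + r$amplitude * outer(spatial, exp(z * t_ref))
    }
  }
  if (noise$sd > 0) {
    set.seed(noise$seed)
    n <- length(data)
    data <- data + complex(real = rnorm(n, 0, noise$sd),
                           imaginary = rnorm(n, 0, noise$sd))
  }
  new_sampled_kspace(tr, data, spectral_dwell, acq_delay, "epe",
                     matrix, fov)
}
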