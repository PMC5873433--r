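## Point-spread-function analysis.  The final k-space weighting of every
## pipeline here is the radial Hamming filter, whose PSF is the 2-D radial
## (Hankel) transform of H over the sampled disk; the chain PSF is the
## reconstruction of a unit point source at the FOV center.

#' Analytic PSF of a radially weighted k-space disk
#'
#' Evaluates \eqn{\mathrm{PSF}(r) = \int_0^{k_{max}} W(k) J_0(2\pi k r)
#' \, 2\pi k \, dk} by adaptive quadrature.
#'
#' @param r Image-domain radii, m.
#' @param filter A [ks_filter] (the weighting W).
#' @return PSF values (same units as the k-space integral).
#' @export
analytic_radial_psf <- function(r, filter) {
  stopifnot(inherits(filter, "ks_filter"))
  vapply(r, function(rr) {
    integrate(function(k) hamming_value(filter, k) *
                besselJ(2 * pi * k * rr, 0) * 2 * pi * k,
              0, filter$k_max, rel.tol = 1e-9)$value
  }, numeric(1))
}

#' Point spread function of a reconstruction chain
#'
#' Pushes a unit point source at the FOV center (constant k-space signal,
#' single FID point) through the trajectory's full reconstruction chain
#' and reports the image together with the full width at half maximum and
#' the first-sidelobe level.
#'
#' @param samples A [sampled_kspace] (geometry carrier; data ignored), or
#'   a [trajectory_spec] (a geometry-only acquisition is synthesized).
#' @param ... Passed to [recon_operator()] / [cartesian_operator()].
#' @param filter Retrospective filter for Cartesian geometries.
#' @return List of class `psf_report`: `image` (matrix, real part),
#'   `fwhm_voxels`, `sidelobe_level` (first sidelobe over main lobe,
#'   magnitude), `profile` (radial profile data.frame).
#' @export
psf <- function(samples, ..., filter = "hamming") {
  if (inherits(samples, "trajectory_spec")) {
    tr <- trajectory_samples(samples)
    samples <- new_sampled_kspace(
      tr, matrix(1 + 0i, nrow(tr), 1), samples$interleaves$spectral_dwell,
      samples$acq_delay, samples$scheme, samples$matrix, samples$fov)
  }
  stopifnot(inherits(samples, "sampled_kspace"))
  op <- if (samples$scheme == "epe") {
    cartesian_operator(samples, filter = filter)
  } else {
    recon_operator(samples, ...)
  }
  img <- op$apply(matrix(1 + 0i, nrow(samples$traj), 1))
  m <- img$matrix
  psf_img <- Re(matrix(img$data[, 1], m, m))
  center <- m / 2 + 1
  peak <- psf_img[center, center]
  ## radial profile through the center row, interpolated for FWHM
  prof <- psf_img[center:(m - 1), center] / peak
  xi <- which(prof < 0.5)[1]
  fwhm <- if (is.na(xi) || xi < 2) NA_real_ else {
    2 * (xi - 2 + (prof[xi - 1] - 0.5) / (prof[xi - 1] - prof[xi]))
  }
  ## first sidelobe: largest magnitude beyond the first zero crossing
  zx <- which(prof <= 0)[1]
  side <- if (is.na(zx)) NA_real_ else max(abs(prof[zx:length(prof)]))
  structure(list(image = psf_img / peak, fwhm_voxels = fwhm,
                 sidelobe_level = side,
                 profile = data.frame(voxel = 0:(length(prof) - 1),
                                      value = prof)),
            class = "psf_report")
}
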