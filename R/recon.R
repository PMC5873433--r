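## Reconstruction chains.
##
## Concentric-circle data: (optional linear phase correction) -> modified
## Pipe-Menon density compensation onto the Hamming target -> Kaiser-
## Bessel gridding (width 3, overgridding 2) -> post-gridding density
## correction -> centered inverse FFT with deapodization -> crop.
## Cartesian (ePE) data: direct FFT with an optional retrospective Hamming
## filter, so that every compared pipeline ends on the same Hamming-
## weighted k-space and hence the same point spread function.

#' Build a linear reconstruction operator for circle data
#'
#' Precomputes the gridding matrix, density-compensation weights, achieved
#' density field and post-correction factor for a trajectory, and returns
#' a closure mapping an `n_samples x n_fid` complex data matrix to a
#' [to_image()] spectral image.  The closure is reused across pseudo-
#' replica noise propagations so every replica sees the identical chain.
#'
#' @param samples A [sampled_kspace] (geometry only is used).
#' @param target A [ks_filter]; default Hamming on `k_outer`.
#' @param overgrid,kernel_width Gridding controls.
#' @param deapodize Image-domain kernel compensation.
#' @param post_correct Apply [post_density_correct()].
#' @param dcf One of `"pipe_menon"`, `"none"` (unit weights).
#' @param phase_correct Apply [linear_phase_correct()] to the data.
#' @param max_iter,tol Pipe-Menon controls.
#' @return List of class `recon_operator`: `apply(data)`, plus the
#'   precomputed `weights`, `S`, `grid_spec`, `achieved`.
#' @export
recon_operator <- function(samples, target = NULL, overgrid = 2,
                           kernel_width = 3, deapodize = TRUE,
                           post_correct = TRUE,
                           dcf = c("pipe_menon", "none"),
                           phase_correct = FALSE,
                           max_iter = 50, tol = 5e-3) {
  stopifnot(inherits(samples, "sampled_kspace"))
  dcf <- match.arg(dcf)
  if (is.null(target))
    target <- ks_filter("hamming", k_outer(samples$matrix, samples$fov))
  gs <- grid_spec(samples$matrix, samples$fov, overgrid, kernel_width)
  S <- gridding_matrix(samples$traj$kx, samples$traj$ky, gs)
  w <- if (dcf == "pipe_menon") {
    pipe_menon_dcf(samples, target, gs, S = S,
                   max_iter = max_iter, tol = tol)$weights
  } else {
    rep(1, nrow(samples$traj))
  }
  achieved <- as.vector(S %*% w)
  dwell <- samples$spectral_dwell
  tau <- samples$traj$tau
  apply_fn <- function(data) {
    data <- as.matrix(data)
    if (phase_correct) {
      nf <- ncol(data)
      f <- fft_freqs(nf, dwell)
      sp <- mvfft(t(data)) * exp(-2i * pi * outer(f, tau))
      data <- t(mvfft(sp, inverse = TRUE)) / nf
    }
    st <- grid_samples(S, data, gs, weights = w)
    if (post_correct) st <- post_density_correct(st, target, achieved)
    to_image(st, deapodize = deapodize)
  }
  structure(list(apply = apply_fn, weights = w, S = S, grid_spec = gs,
                 achieved = achieved, target = target,
                 n_samples = nrow(samples$traj)),
            class = "recon_operator")
}

#' Build the Cartesian (ePE) reconstruction operator
#'
#' Places samples on their native grid cells, applies a retrospective
#' radial filter (`"hamming"` to match the density-weighted pipelines,
#' `"none"` for an unfiltered uniform-density reference) and inverse
#' Fourier transforms.
#'
#' @param samples A [sampled_kspace] from [acquire_epe()].
#' @param filter `"hamming"` or `"none"`.
#' @return A `recon_operator`.
#' @export
cartesian_operator <- function(samples, filter = c("hamming", "none")) {
  stopifnot(inherits(samples, "sampled_kspace"), samples$scheme == "epe")
  filter <- match.arg(filter)
  m <- samples$matrix
  ko <- k_outer(m, samples$fov)
  kr <- sqrt(samples$traj$kx^2 + samples$traj$ky^2)
  wf <- if (filter == "hamming") {
    hamming_value(ks_filter("hamming", ko), kr)
  } else rep(1, length(kr))
  idx <- samples$traj$ix + (samples$traj$iy - 1) * m
  apply_fn <- function(data) {
    data <- as.matrix(data)
    nf <- ncol(data)
    out <- matrix(0i, m * m, nf)
    for (j in seq_len(nf)) {
      plane <- matrix(0i, m, m)
      plane[idx] <- data[, j] * wf
      out[, j] <- as.vector(ifft2_centered(plane))
    }
    structure(list(data = out, matrix = m, fov = samples$fov,
                   voxel_size = samples$fov / m, n_fid = nf,
                   domain = "time", spectral_dwell = NA_real_),
              class = "spectral_image")
  }
  structure(list(apply = apply_fn, weights = wf, grid_spec = NULL,
                 n_samples = nrow(samples$traj), filter = filter),
            class = "recon_operator")
}

#' Reconstruct a sampled acquisition
#'
#' Convenience wrapper: builds the appropriate operator for the scheme and
#' applies it to the acquired data.
#'
#' @param samples A [sampled_kspace].
#' @param ... Passed to [recon_operator()] (ignored for Cartesian data
#'   beyond `filter`).
#' @param filter Retrospective filter for Cartesian data.
#' @return A `spectral_image` (time domain).
#' @export
reconstruct <- function(samples, ..., filter = "hamming") {
  op <- if (samples$scheme == "epe") {
    cartesian_operator(samples, filter = filter)
  } else {
    recon_operator(samples, ...)
  }
  op$apply(samples$data)
}

#' Direct DFT reconstruction (oracle)
#'
#' Brute-force conjugate-phase sum \eqn{I(x) = \sum_s w_s d_s e^{2\pi i
#' k_s \cdot x}} on the voxel grid -- the independent reference the
#' gridding chain is validated against on small problems.
#'
#' @param samples A [sampled_kspace].
#' @param weights Per-sample weights (e.g. a Pipe-Menon solution).
#' @param fid Column of the data matrix to reconstruct.
#' @return Complex `matrix x matrix` image.
#' @export
dft_reconstruct <- function(samples, weights, fid = 1) {
  m <- samples$matrix
  x <- (seq_len(m) - 1 - m / 2) * samples$fov / m
  d <- samples$data[, fid] * weights
  ex <- exp(2i * pi * outer(x, samples$traj$kx))   # m x n_samples
  ey <- exp(2i * pi * outer(samples$traj$ky, x))   # n_samples x m
  ex %*% (d * ey)
}
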