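## Kaiser-Bessel convolution gridding of non-Cartesian k-space samples.
##
## The kernel width is 3 grid cells and the overgridding factor 2 (the
## shape parameter beta follows the standard optimal formula for that
## pair).  Gridding is expressed as a sparse deposit matrix so that the
## full spectral stack (one k-space plane per FID point) is a single
## sparse-times-dense product, and so the Pipe-Menon density iteration can
## reuse the same operator.

#' Cartesian grid specification for gridding
#'
#' @param matrix Intended image matrix (voxels per side).
#' @param fov Field of view, m.
#' @param overgrid Overgridding factor (2 for reconstruction, 1 for
#'   density measurements).
#' @param kernel_width Kaiser-Bessel kernel width in grid cells.
#' @param pad Extra cells appended on each side (used for density
#'   measurements so the outermost circle's kernel footprint is not
#'   clipped; must be 0 when the grid is Fourier transformed).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(matrix, fov, overgrid = 2, kernel_width = 3, pad = 0) {
  stopifnot(matrix %% 2 == 0, overgrid >= 1, kernel_width >= 2)
  n <- as.integer(round(matrix * overgrid)) + 2L * as.integer(pad)
  ## standard optimal Kaiser-Bessel shape for this width/overgridding pair
  beta <- pi * sqrt((kernel_width / overgrid)^2 * (overgrid - 0.5)^2 - 0.8)
  w_half <- kernel_width / 2
  ## kernel normalized so the integer-sampled footprint sums to ~1
  raw <- function(d) {
    z <- 1 - (d / w_half)^2
    ifelse(z > 0, besselI(beta * sqrt(pmax(z, 0)), 0), 0)
  }
  norm <- sum(raw(seq(-floor(w_half), floor(w_half))))
  structure(list(
    matrix = matrix, fov = fov, overgrid = overgrid,
    kernel_width = kernel_width, beta = beta, pad = as.integer(pad),
    n_cells = n, dk = 1 / (overgrid * fov),
    kernel = function(d) raw(d) / norm
  ), class = "grid_spec")
}

## k-space radius of every grid cell, as an n x n matrix.
grid_cell_radii <- function(gs) {
  cc <- (seq_len(gs$n_cells) - 1 - gs$n_cells / 2) * gs$dk
  sqrt(outer(cc^2, cc^2, "+"))
}

#' Sparse gridding (deposit) matrix for a set of sample positions
#'
#' Builds the `n_cells^2 x n_samples` sparse matrix `S` whose action on a
#' vector of per-sample values performs Kaiser-Bessel convolution gridding
#' onto the Cartesian grid.  `t(S) S w` evaluates the gridding convolution
#' back at the sample positions (the operator at the heart of the
#' Pipe-Menon iteration).
#'
#' @param kx,ky Sample positions, 1/m.
#' @param gs A [grid_spec].
#' @return A `dgCMatrix`.
#' @export
gridding_matrix <- function(kx, ky, gs) {
  stopifnot(inherits(gs, "grid_spec"), length(kx) == length(ky))
  n <- gs$n_cells
  w_half <- gs$kernel_width / 2
  ## continuous cell coordinate (1-based): cell j has center (j - 1 - n/2) dk
  ux <- kx / gs$dk + n / 2 + 1
  uy <- ky / gs$dk + n / 2 + 1
  if (any(ux < 1 - w_half | ux > n + w_half |
          uy < 1 - w_half | uy > n + w_half))
    stopf("samples beyond the grid extent")
  offs <- seq(-ceiling(w_half), ceiling(w_half))
  ns <- length(kx)
  ii <- jj <- xx <- vector("list", length(offs)^2)
  m <- 0L
  wrap <- function(c) ((c - 1) %% n) + 1  # circular (periodic k-space) wrap
  for (ox in offs) {
    cx <- floor(ux) + ox
    wx <- gs$kernel(cx - ux)
    for (oy in offs) {
      cy <- floor(uy) + oy
      wy <- gs$kernel(cy - uy)
      w <- wx * wy
      keep <- which(w > 0)
      if (length(keep)) {
        m <- m + 1L
        ii[[m]] <- wrap(cx[keep]) + (wrap(cy[keep]) - 1) * n
        jj[[m]] <- keep
        xx[[m]] <- w[keep]
      }
    }
  }
  Matrix::sparseMatrix(i = unlist(ii[seq_len(m)]), j = unlist(jj[seq_len(m)]),
                       x = unlist(xx[seq_len(m)]), dims = c(n * n, ns))
}

## Complex sparse-times-dense product (Matrix only handles numeric).
sp_mult <- function(S, x) {
  if (is.complex(x)) {
    as.matrix(S %*% Re(x)) + 1i * as.matrix(S %*% Im(x))
  } else {
    as.matrix(S %*% x)
  }
}

#' Grid weighted samples onto the Cartesian k-space grid
#'
#' Deposits `weights * data` through the Kaiser-Bessel kernel.  `data` may
#' be a vector (one k-space plane) or an `n_samples x n_fid` matrix (one
#' plane per FID point, gridded in a single sparse product).
#'
#' @param S Sparse matrix from [gridding_matrix()].
#' @param data Complex per-sample values.
#' @param weights Per-sample density-compensation weights (default 1).
#' @param gs The [grid_spec] used to build `S`.
#' @return Complex matrix `n_cells^2 x n_fid` (class `grid_stack`, with
#'   the grid spec attached).
#' @export
grid_samples <- function(S, data, gs, weights = NULL) {
  data <- as.matrix(data)
  if (!is.null(weights)) data <- data * weights
  out <- sp_mult(S, data)
  attr(out, "grid_spec") <- gs
  class(out) <- c("grid_stack", class(out))
  out
}

#' Post-gridding density correction
#'
#' Removes the small deviations of the achieved (gridded) density from the
#' kernel-blurred target density that remain after pre-gridding density
#' compensation.  Each cell of the stack is multiplied by
#' `blur(target) / max(achieved, eps)`, where `blur(target)` is the target
#' filter sampled on the grid cells, convolved with the same gridding
#' kernel (so the correction fixes density deviations only and does not
#' fight the image-domain deapodization); cells outside the sampled disk
#' are set to zero.
#'
#' @param stack A `grid_stack` from [grid_samples()].
#' @param target A [ks_filter] (the Hamming target).
#' @param achieved Achieved density field: the gridding of the DCF weights
#'   alone (`n_cells^2` real vector).
#' @param eps_frac Regularization floor as a fraction of `max(achieved)`.
#' @return Corrected stack (same class/shape).
#' @export
post_density_correct <- function(stack, target, achieved, eps_frac = 1e-3) {
  gs <- attr(stack, "grid_spec")
  stopifnot(inherits(gs, "grid_spec"), inherits(target, "ks_filter"))
  kr <- grid_cell_radii(gs)
  tgt <- matrix(0, gs$n_cells, gs$n_cells)
  inside <- kr <= target$k_max
  tgt[inside] <- hamming_value(target, kr[inside])
  tgt_blur <- kernel_blur(tgt, gs)
  achieved <- as.vector(achieved)
  floor_val <- eps_frac * max(achieved)
  fac <- as.vector(tgt_blur) / pmax(achieved, floor_val)
  fac[as.vector(kr) > target$k_max + gs$kernel_width * gs$dk] <- 0
  out <- stack * fac
  attr(out, "grid_spec") <- gs
  class(out) <- class(stack)
  out
}

## Convolve a cell field with the separable integer-sampled kernel.
kernel_blur <- function(field, gs) {
  offs <- seq(-floor(gs$kernel_width / 2), floor(gs$kernel_width / 2))
  w <- gs$kernel(offs)
  w <- w / sum(w)
  blur1 <- function(m) {
    out <- m * w[offs == 0]
    n <- nrow(m)
    for (i in seq_along(offs)) {
      o <- offs[i]
      if (o == 0) next
      src <- seq_len(n) - o
      ok <- src >= 1 & src <= n
      shifted <- matrix(0, n, ncol(m))
      shifted[ok, ] <- m[src[ok], ]
      out <- out + w[i] * shifted
    }
    out
  }
  t(blur1(t(blur1(field))))
}

## Image-domain deapodization profile: continuous Fourier transform of the
## gridding kernel evaluated at the image pixel positions (fine quadrature;
## the kernel has compact support so a plain Riemann sum suffices).
deapodization <- function(gs) {
  n <- gs$n_cells
  w_half <- gs$kernel_width / 2
  u <- seq(-w_half, w_half, length.out = 3001)
  cu <- gs$kernel(u)
  du <- u[2] - u[1]
  p <- seq_len(n) - 1 - n / 2
  vapply(p, function(pp) sum(cu * cos(2 * pi * u * pp / n)) * du, numeric(1))
}

#' Transform a gridded k-space stack to the image domain
#'
#' Per FID point: centered 2-D inverse FFT of the oversampled grid,
#' image-domain deapodization by the kernel transform (default on), and a
#' central crop to `matrix x matrix` voxels (half-open window, DC at
#' 0-based index `matrix/2`).
#'
#' @param stack A `grid_stack` (requires `pad = 0` in its grid spec).
#' @param deapodize Divide by the kernel's image-domain transform.
#' @return An object of class `spectral_image`: complex matrix
#'   `matrix^2 x n_fid` of voxel FIDs plus geometry fields.
#' @export
to_image <- function(stack, deapodize = TRUE) {
  gs <- attr(stack, "grid_spec")
  stopifnot(inherits(gs, "grid_spec"))
  if (gs$pad != 0) stopf("cannot Fourier transform a padded density grid")
  n <- gs$n_cells
  m <- gs$matrix
  dea <- if (deapodize) deapodization(gs) else rep(1, n)
  keep <- (n / 2 - m / 2 + 1):(n / 2 + m / 2)
  nf <- ncol(stack)
  out <- matrix(0i, m * m, nf)
  for (j in seq_len(nf)) {
    img <- ifft2_centered(matrix(stack[, j], n, n))
    img <- img / outer(dea, dea)
    out[, j] <- as.vector(img[keep, keep])
  }
  structure(list(
    data = out, matrix = m, fov = gs$fov,
    voxel_size = gs$fov / m, n_fid = nf,
    domain = "time", spectral_dwell = NA_real_
  ), class = "spectral_image")
}

#' Per-voxel spectra of a spectral image
#'
#' FFT over the spectral (FID) axis of every voxel; the frequency axis is
#' returned in Hz (and ppm for a given spectrometer frequency).
#'
#' @param image A `spectral_image` in the time domain.
#' @param spectral_dwell Spectral dwell time, s.
#' @param f0_mhz Spectrometer reference frequency, MHz (297.2 for proton
#'   at 7 T), used only for the ppm axis.
#' @return A `spectral_image` with `domain = "frequency"` and axes
#'   `freq_hz`, `ppm`.
#' @export
spectra <- function(image, spectral_dwell, f0_mhz = 297.2) {
  stopifnot(inherits(image, "spectral_image"), image$domain == "time")
  sp <- t(mvfft(t(image$data)))  # FFT along the fid dimension, per voxel
  f <- fft_freqs(image$n_fid, spectral_dwell)
  out <- image
  out$data <- sp
  out$domain <- "frequency"
  out$spectral_dwell <- spectral_dwell
  out$freq_hz <- f
  out$ppm <- f / f0_mhz
  out
}
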