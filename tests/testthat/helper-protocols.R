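# Shared fixture builders: everything is generated in code at test time.

FOV <- 0.22

# Small desk-scale protocol (single interleave, short FID) used by the
# reconstruction and simulation tests.
tiny_spec <- function(scheme = "dw_concept", matrix = 16, n_fid = 1, ...) {
  trajectory_spec(scheme, matrix = matrix, fov = FOV,
                  n_interleaves = 1, n_fid_points = n_fid, ...)
}

# Analytic image of a centered radial phantom seen through a Hamming
# k-space window: the Hankel-transform ground truth used by the
# inverse-crime checks.
hamming_blurred_disk <- function(radius_m, matrix, fov) {
  ko <- k_outer(matrix, fov)
  H <- function(k) 0.54 + 0.46 * cos(pi * k / ko)
  Fd <- function(k) ifelse(k < 1e-9, pi * radius_m^2,
                           radius_m * besselJ(2 * pi * radius_m * k, 1) / k)
  x <- (seq_len(matrix) - 1 - matrix / 2) * fov / matrix
  rr <- sqrt(outer(x^2, x^2, "+"))
  kk <- seq(0, ko, length.out = 2048)
  dk <- kk[2] - kk[1]
  wts <- H(kk) * Fd(kk) * 2 * pi * kk * dk
  vals <- vapply(as.vector(rr), function(r) sum(wts * besselJ(2 * pi * kk * r, 0)),
                 numeric(1))
  matrix(vals, matrix, matrix)
}
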