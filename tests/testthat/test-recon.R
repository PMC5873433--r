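# Gridding reconstruction chain: kernel normalization, density
# compensation, post-gridding correction, image transform, spectra, phase
# correction and the point spread function.

test_that("a unit sample deposits a normalized kernel footprint", {
  gs <- grid_spec(16, FOV)
  for (kpos in list(c(0, 0), c(3.1, -7.7), c(20.02, 11.5))) {
    S <- gridding_matrix(kpos[1], kpos[2], gs)
    expect_equal(sum(S), 1, tolerance = 1e-2)  # sub-cell ripple bound
  }
  expect_error(gridding_matrix(1e4, 0, gs), "beyond the grid")
})

test_that("Pipe-Menon weights are radially symmetric and follow k H(k) for e-circles", {
  acq <- acquire(phantom_preset("single_disk", FOV), tiny_spec("e_concept", 32))
  ko <- k_outer(32, FOV)
  dcf <- pipe_menon_dcf(acq, ks_filter("hamming", ko), grid_spec(32, FOV))
  expect_true(all(dcf$weights >= 0))
  expect_true(dcf$converged)
  per_circle <- tapply(dcf$weights, acq$traj$circle, mean)
  spread <- tapply(dcf$weights, acq$traj$circle, sd) / per_circle
  expect_lt(max(spread), 1e-10)  # symmetrized fixed point
  # annulus-area oracle: weights proportional to k_i H(k_i) (interior circles)
  r <- circle_radii("e_concept", 32, FOV)
  ref <- r * hamming_value(ks_filter("hamming", ko), r)
  i <- 3:14
  s <- sum(ref[i] * per_circle[i]) / sum(per_circle[i]^2)
  expect_lt(max(abs(s * per_circle[i] - ref[i]) / ref[i]), 0.02)
})

test_that("DCF-compensated DW sampling grids to the Hamming density", {
  spec <- tiny_spec("dw_concept", 64)
  acq <- acquire(phantom_preset("single_disk", FOV), spec)
  op <- recon_operator(acq)
  # grid the weighted unit samples at overgridding 1 (density measurement)
  prof <- empirical_density(acq, FOV, 64, weights = op$weights)
  expect_lt(density_rms_error(prof, function(k) hamming_value(op$target, k)),
            0.02)
})

test_that("gridding reconstruction matches the direct DFT oracle", {
  for (ph in list(phantom_preset("single_disk", FOV),
                  phantom_preset("localization", FOV))) {
    acq <- acquire(ph, tiny_spec("dw_concept", 16))
    op <- recon_operator(acq, post_correct = FALSE)
    img <- matrix(op$apply(acq$data)$data[, 1], 16, 16)
    oracle <- dft_reconstruct(acq, op$weights)
    expect_lt(rel_rms(img, oracle), 3e-3)
    expect_lt(sqrt(mean(Mod(img - oracle)^2)) / max(Mod(oracle)), 1.2e-3)
  }
})

test_that("post-gridding correction is the identity when achieved = blurred target", {
  gs <- grid_spec(16, FOV)
  ko <- k_outer(16, FOV)
  target <- ks_filter("hamming", ko)
  kr <- dwconcept:::grid_cell_radii(gs)
  tgt <- matrix(0, gs$n_cells, gs$n_cells)
  tgt[kr <= ko] <- hamming_value(target, kr[kr <= ko])
  ach <- dwconcept:::kernel_blur(tgt, gs)
  stack <- matrix(complex(real = rnorm(gs$n_cells^2), imaginary = rnorm(gs$n_cells^2)))
  attr(stack, "grid_spec") <- gs
  class(stack) <- c("grid_stack", class(stack))
  out <- post_density_correct(stack, target, as.vector(ach))
  inside <- as.vector(kr) <= 0.9 * ko
  expect_equal(out[inside, 1], stack[inside, 1], tolerance = 1e-9)
  # cells far outside the sampled disk are zeroed
  outside <- as.vector(kr) > ko + 3 * gs$dk
  expect_true(all(out[outside, 1] == 0))
})

test_that("to_image round-trips with its exact inverse when deapodizing", {
  gs <- grid_spec(16, FOV)
  n <- gs$n_cells
  set.seed(3)
  stack <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n * n, 1)
  attr(stack, "grid_spec") <- gs
  class(stack) <- c("grid_stack", class(stack))
  img <- to_image(stack, deapodize = TRUE)
  # invert: re-apodize the full-grid image, forward FFT, compare
  full <- dwconcept:::ifft2_centered(matrix(stack[, 1], n, n))
  dea <- dwconcept:::deapodization(gs)
  img_full <- full / outer(dea, dea)
  back <- dwconcept:::fftshift2(fft(dwconcept:::fftshift2(img_full * outer(dea, dea)))) / n^2
  expect_lt(rel_rms(back, matrix(stack[, 1], n, n)), 1e-10)
  # and the crop keeps the central half-open window (DC at matrix/2, 0-based)
  keep <- (n / 2 - 8 + 1):(n / 2 + 8)
  expect_equal(matrix(img$data[, 1], 16, 16), img_full[keep, keep],
               tolerance = 1e-12)
})

test_that("spectra: Lorentzian peak lands in the right bin, Parseval holds", {
  dwell <- 5e-4
  nf <- 64
  f0 <- 300
  t <- (0:(nf - 1)) * dwell
  fid <- exp((2i * pi * f0 - 1 / 0.05) * t)
  img <- structure(list(data = matrix(fid, 1, nf, byrow = TRUE), matrix = 1,
                        fov = FOV, voxel_size = FOV, n_fid = nf,
                        domain = "time", spectral_dwell = NA_real_),
                   class = "spectral_image")
  sp <- spectra(img, dwell)
  peak <- which.max(Mod(sp$data[1, ]))
  expect_lt(abs(sp$freq_hz[peak] - f0), 1 / (nf * dwell) + 1e-9)
  expect_equal(sum(Mod(sp$data)^2) / nf, sum(Mod(fid)^2), tolerance = 1e-12)
  expect_equal(sp$ppm, sp$freq_hz / 297.2)
  zero <- img; zero$data[] <- 0i
  expect_true(all(Mod(spectra(zero, dwell)$data) == 0))
})

test_that("linear phase correction is exact for on-resonance data and tau = 0", {
  spec <- tiny_spec("dw_concept", 16, n_fid = 8)
  ph <- phantom_preset("single_disk", FOV)
  acq <- acquire(ph, spec)
  # tau = 0 reference: identity
  acq0 <- acq
  acq0$traj$tau <- rep(0, nrow(acq0$traj))
  fixed0 <- linear_phase_correct(acq0)
  expect_equal(fixed0$data, acq0$data, tolerance = 1e-10)
  # static on-resonance phantom: series is constant, correction is identity
  static <- mrsi_phantom(list(phantom_shape("disk", c(0.02, 0), c(0.03, 0.03),
    resonances = data.frame(freq_hz = 0, amplitude = 1, t2star_s = 1e6))), FOV)
  acq_s <- acquire(static, spec)
  expect_equal(linear_phase_correct(acq_s)$data, acq_s$data, tolerance = 1e-8)
})

test_that("phase correction recovers the revolution-start reference of an off-resonance source", {
  # off-center small disk at +1000 Hz: ~150 degrees of phase evolution
  # along each revolution, well inside the single-interleave bandwidth
  spec <- trajectory_spec("dw_concept", 16, FOV, n_interleaves = 1,
                          n_fid_points = 32)
  ph <- mrsi_phantom(list(phantom_shape("disk", c(0.05, -0.03), c(0.02, 0.02),
    resonances = data.frame(freq_hz = 1000, amplitude = 1, t2star_s = 0.05))), FOV)
  acq <- acquire(ph, spec)
  # ground truth: the same samples referred to the revolution start
  t_ref <- spec$acq_delay +
    (0:(spec$n_fid_points - 1)) * spec$interleaves$spectral_dwell
  spatial <- dwconcept:::shape_ktransform(ph$shapes[[1]], acq$traj$kx, acq$traj$ky)
  ideal <- acq
  ideal$data <- outer(spatial, exp((2i * pi * 1000 - 1 / 0.05) * t_ref))
  fixed <- linear_phase_correct(acq)
  expect_lt(rel_rms(fixed$data, ideal$data),
            0.1 * rel_rms(acq$data, ideal$data))
  # image domain: the corrected chain matches the ideal-chain peak to < 5%
  # on an interior FID plane (the DFT-based ramp has wrap-around error at
  # the first/last spectral samples, like any frequency-domain shift)
  op <- recon_operator(acq, phase_correct = TRUE)
  op_plain <- recon_operator(acq, phase_correct = FALSE)
  peak_c <- max(Mod(op$apply(acq$data)$data[, 16]))
  peak_i <- max(Mod(op_plain$apply(ideal$data)$data[, 16]))
  expect_lt(abs(peak_c - peak_i) / peak_i, 0.05)
})

test_that("DW chain PSF matches the analytic Hamming-apodized disk transform", {
  M <- 32
  p <- psf(tiny_spec("dw_concept", M))
  x <- (seq_len(M) - 1 - M / 2) * FOV / M
  rr <- sqrt(outer(x^2, x^2, "+"))
  ref <- matrix(analytic_radial_psf(as.vector(rr),
                                    ks_filter("hamming", k_outer(M, FOV))), M, M)
  ref <- ref / max(ref)
  expect_lt(sqrt(mean((p$image - ref)^2)), 0.01)
  expect_true(p$fwhm_voxels > 1.5 && p$fwhm_voxels < 2.5)
})

test_that("Hamming apodization suppresses the sidelobes of the uniform PSF", {
  samples <- acquire_epe(mrsi_phantom(list(), FOV), 32, FOV, 1, 5.4e-4)
  p_ham <- psf(samples, filter = "hamming")
  p_uni <- psf(samples, filter = "none")
  expect_gt(p_uni$sidelobe_level, 3 * p_ham$sidelobe_level)
})
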