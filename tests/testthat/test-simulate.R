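# Analytic phantoms, forward acquisition, noise, pseudo-replica SNR and
# the end-to-end experiments.

test_that("analytic k-signal has the exact DC value and decays in time", {
  ph <- mrsi_phantom(list(
    phantom_shape("disk", c(0.01, 0), c(0.03, 0.03)),
    phantom_shape("ellipse", c(-0.02, 0.02), c(0.04, 0.02), rotation = 0.5,
                  resonances = data.frame(freq_hz = 0, amplitude = 2,
                                          t2star_s = 0.05))), FOV)
  dc <- analytic_ksignal(ph, 0, 0, 0)
  expect_equal(Re(dc), pi * 0.03^2 * 1 + pi * 0.04 * 0.02 * 2, tolerance = 1e-12)
  expect_equal(Im(dc), 0, tolerance = 1e-12)
  expect_lt(Mod(analytic_ksignal(ph, 0, 0, 5)), 1e-12)
  expect_error(analytic_ksignal(ph, 0, 0, -1))
})

test_that("disk transform matches a rasterized-FFT oracle", {
  a <- 0.05
  ph <- mrsi_phantom(list(phantom_shape("disk", c(0, 0), c(a, a))), FOV)
  # rasterize on a fine grid spanning 2 FOV (so the k-grid step is 1/(2 FOV))
  N <- 1024
  ext <- 2 * FOV
  x <- (seq_len(N) - 1 - N / 2) * ext / N
  img <- outer(x, x, function(xx, yy) as.numeric(xx^2 + yy^2 <= a^2))
  F <- dwconcept:::fftshift2(fft(dwconcept:::fftshift2(img))) * (ext / N)^2
  ko <- k_outer(64, FOV)
  ci <- (seq_len(N) - 1 - N / 2) / ext
  sel <- which(abs(ci) <= ko)
  ref <- analytic_ksignal(ph, rep(ci[sel], length(sel)),
                          rep(ci[sel], each = length(sel)), 0)
  got <- as.vector(F[sel, sel])
  expect_lt(max(Mod(got - ref)) / Mod(ref[which.max(Mod(ref))]), 5e-3)
})

test_that("acquisition is deterministic per seed with additive noise", {
  ph <- phantom_preset("single_disk", FOV)
  spec <- tiny_spec("dw_concept", 16, n_fid = 4)
  clean <- acquire(ph, spec)
  a1 <- acquire(ph, spec, noise_model(0.1, 42))
  a2 <- acquire(ph, spec, noise_model(0.1, 42))
  a3 <- acquire(ph, spec, noise_model(0.1, 43))
  expect_identical(a1$data, a2$data)
  expect_false(identical(a1$data, a3$data))
  n <- a1$data - clean$data
  expect_equal(sd(Re(n)), 0.1, tolerance = 0.05)
  expect_equal(sd(Im(n)), 0.1, tolerance = 0.05)
  expect_lt(abs(mean(Re(n))), 0.005)
})

test_that("a static on-resonance phantom gives identical revolutions", {
  static <- mrsi_phantom(list(phantom_shape("disk", c(0.02, 0), c(0.03, 0.03),
    resonances = data.frame(freq_hz = 0, amplitude = 1, t2star_s = 1e9))), FOV)
  acq <- acquire(static, tiny_spec("e_concept", 16, n_fid = 5))
  for (j in 2:5) expect_equal(acq$data[, j], acq$data[, 1], tolerance = 1e-9)
})

test_that("pseudo-replica SNR scales inversely with the noise level", {
  ph <- phantom_preset("smooth_blob", FOV)
  spec <- tiny_spec("dw_concept", 16, n_fid = 8)
  acq <- acquire(ph, spec)
  op <- recon_operator(acq)
  r1 <- pseudo_replica_snr(op, acq, noise_model(0.01, 5), 32)
  r2 <- pseudo_replica_snr(op, acq, noise_model(0.02, 6), 32)
  mask <- phantom_mask(ph, 16)
  expect_equal(mean(r1$snr[mask]) / mean(r2$snr[mask]), 2, tolerance = 0.2)
  expect_error(pseudo_replica_snr(op, acq, noise_model(0, 1), 32), "zero noise")
  expect_error(pseudo_replica_snr(op, acq, noise_model(0.01, 1), 8), ">= 16")
})

test_that("single-voxel Cartesian SNR matches the closed form", {
  # uniform-density Cartesian acquisition, no filter: every voxel's noise
  # is sd * sqrt(n_fid * n_points) per spectral bin (unnormalized FFTs),
  # and the DC-object signal spectrum peaks at n_points * n_fid * A.
  M <- 8; nf <- 16; sdn <- 0.05
  ph <- mrsi_phantom(list(phantom_shape("gaussian", c(0, 0), c(0.04, 0.04),
    resonances = data.frame(freq_hz = 0, amplitude = 3, t2star_s = 1e9))), 0.22)
  acq <- acquire_epe(ph, M, 0.22, nf, 5.4e-4)
  op <- cartesian_operator(acq, filter = "none")
  rep <- pseudo_replica_snr(op, acq, noise_model(sdn, 9), 256)
  n_pts <- nrow(acq$traj)
  center <- M / 2 * M + M / 2 + 1  # (M/2, M/2) 0-based -> linear index
  img0 <- op$apply(acq$data)
  sig_expect <- Mod(sum(acq$data[, 1])) * nf  # spectral DC peak of that voxel
  noise_expect <- sdn * sqrt(n_pts * nf)
  expect_equal(rep$snr[M / 2 + 1, M / 2 + 1],
               sig_expect / noise_expect, tolerance = 0.1)
})

test_that("reconstructed amplitude is linear in the true amplitude", {
  spec <- tiny_spec("dw_concept", 16)
  amps <- c(0.1, 1, 10)
  peaks <- vapply(amps, function(A) {
    ph <- mrsi_phantom(list(phantom_shape("disk", c(0, 0), c(0.04, 0.04),
      resonances = data.frame(freq_hz = 0, amplitude = A, t2star_s = 0.05))), FOV)
    acq <- acquire(ph, spec)
    max(Mod(recon_operator(acq)$apply(acq$data)$data))
  }, numeric(1))
  expect_gt(cor(peaks, amps)^2, 0.999)
  expect_equal(peaks[3] / peaks[1], 100, tolerance = 1e-6)
})

test_that("no inverse crime: gridded recon agrees with the Hankel ground truth", {
  M <- 32
  radius <- 0.28 * FOV
  ph <- mrsi_phantom(list(phantom_shape("disk", c(0, 0), c(radius, radius))), FOV)
  acq <- acquire(ph, tiny_spec("dw_concept", M))
  img <- Re(matrix(recon_operator(acq)$apply(acq$data)$data[, 1], M, M))
  truth <- hamming_blurred_disk(radius, M, FOV)
  mask <- phantom_mask(ph, M, shrink = 0.75)
  s <- sum(truth[mask] * img[mask]) / sum(img[mask]^2)
  expect_lt(sqrt(mean((s * img[mask] - truth[mask])^2)) /
              sqrt(mean(truth[mask]^2)), 0.02)
})

test_that("empty phantom reconstructs to numerical zero", {
  ph <- mrsi_phantom(list(), FOV)
  acq <- acquire(ph, tiny_spec("dw_concept", 16))
  img <- recon_operator(acq)$apply(acq$data)
  expect_lt(max(Mod(img$data)), 1e-12)
})

test_that("localization: no-DCF equidistant circles bleed, Hamming chains do not", {
  loc <- experiment_localization(matrix = 32, fov = FOV)
  expect_gt(loc$leakage["e_nodcf"], 2 * loc$leakage["dw"])
  expect_gt(loc$leakage["e_nodcf"], 2 * loc$leakage["e_pm"])
  expect_true(all(loc$psf_rms < 0.01))
})

test_that("Monte-Carlo SNR ratios approach the analytic values (small run)", {
  # 48 replicas: a fast smoke version of the acceptance-scale experiment
  ex <- experiment_snr_ratios(matrix = 32, n_fid_points = 32,
                              n_replicas = 48, seed = 3)
  expect_equal(unname(ex$ratios["dw_vs_e"]), 1.090, tolerance = 0.03)
  expect_equal(unname(ex$ratios["dw_vs_epe"]), 1.252, tolerance = 0.05)
  expect_gt(ex$ratios["e_vs_epe"], 1.05)
})
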