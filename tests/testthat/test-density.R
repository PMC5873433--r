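# Density algebra: the Hamming filter, the noise-variance functional and
# the relative-SNR ratios, checked against closed-form integrals computed
# independently in this file.

# Closed-form moments of H(k) = a + b cos(pi k / kmax) over the unit disk
# (kmax = 1, measure 2 pi k dk), derived by hand:
#   I1 = int H      = 2 pi (a/2 - 2 b / pi^2)
#   I2 = int H^2    = 2 pi (a^2/2 - 4 a b / pi^2 + b^2/4)
#   I3 = int H^2 k  = a^2/3 - 4 a b / pi^2 + b^2 (1/6 + 1/(4 pi^2))
a <- 0.54
b <- 0.46
I1 <- 2 * pi * (a / 2 - 2 * b / pi^2)
I2 <- 2 * pi * (a^2 / 2 - 4 * a * b / pi^2 + b^2 / 4)
I3 <- a^2 / 3 - 4 * a * b / pi^2 + b^2 * (1 / 6 + 1 / (4 * pi^2))

test_that("hamming_value matches the window definition and guards its domain", {
  f <- ks_filter("hamming", k_max = 100)
  expect_equal(hamming_value(f, 0), 1.00)
  expect_equal(hamming_value(f, 100), 0.08)
  expect_equal(hamming_value(f, 50), 0.54)
  expect_error(hamming_value(f, -1), "domain")
  expect_error(hamming_value(f, 101), "domain")
  expect_error(ks_filter("hamming", 1, alpha = 0.4, beta = 0.46), "alpha > beta")
  expect_error(ks_filter("hamming", 1, alpha = 0.7, beta = 0.5), "<= 1")
})

test_that("noise_variance reproduces closed-form values for matched profiles", {
  U <- density_uniform(1)
  H <- density_from_filter(ks_filter("hamming", 1))
  # rho_T = rho_A: sigma^2 = total time = 1 after normalization
  expect_equal(noise_variance(U, U)$sigma_squared, 1, tolerance = 1e-8)
  expect_equal(noise_variance(H, H)$sigma_squared, 1, tolerance = 1e-8)
  # uniform acquisition of a Hamming target: pi * I2 / I1^2
  expect_equal(noise_variance(H, U)$sigma_squared, pi * I2 / I1^2,
               tolerance = 1e-6)
  # 1/k acquisition of a Hamming target: (4 pi^2 / I1^2) * I3
  expect_equal(noise_variance(H, density_inverse_k(1))$sigma_squared,
               4 * pi^2 * I3 / I1^2, tolerance = 1e-6)
  expect_error(noise_variance(H, density_uniform(2)), "k_max")
  zero_mid <- density_profile(function(k) pmax(0, abs(k - 0.5) - 0.1), 1)
  expect_error(noise_variance(H, zero_mid), "singular")
})

test_that("relative_snr reproduces the density-weighting theory ratios", {
  tab <- snr_theory_table()
  expect_equal(unname(tab["hamming_vs_uniform"]), sqrt(pi * I2) / I1,
               tolerance = 1e-6)
  expect_equal(unname(tab["hamming_vs_uniform"]), 1.2523, tolerance = 2e-4)
  expect_equal(unname(tab["inverse_k_vs_uniform"]), 1.1486, tolerance = 2e-4)
  expect_equal(unname(tab["hamming_vs_inverse_k"]), 1.0903, tolerance = 2e-4)
  U <- density_uniform(1)
  expect_equal(relative_snr(U, U), 1, tolerance = 1e-8)
  # ratios do not depend on the physical k_max scale
  expect_equal(unname(snr_theory_table(145.45)), unname(tab), tolerance = 1e-8)
})

test_that("matched density is SNR-optimal among perturbed acquisitions", {
  H <- ks_filter("hamming", 1)
  target <- density_from_filter(H)
  best <- relative_snr(target, target)
  set.seed(11)
  for (i in 1:12) {
    amp <- runif(1, 0.05, 0.5)
    mode <- sample(1:4, 1)
    phase <- runif(1, 0, 2 * pi)
    pert <- density_profile(function(k) {
      hamming_value(H, k) * (1 + amp * sin(mode * pi * k + phase))
    }, 1)
    expect_lt(relative_snr(pert, target), best)
  }
})

test_that("empirical density recovers 1/k for equidistant and Hamming for DW circles", {
  # at the published matrix: smaller matrices leave the anchored innermost
  # circle's density surplus within the comparison window (and the 1/k
  # ladder becomes visibly ringy between 2-cell-spaced rings)
  ko64 <- k_outer(64, FOV)
  prof_dw <- empirical_density(trajectory_samples(tiny_spec("dw_concept", 64)),
                               FOV, 64)
  expect_lt(density_rms_error(prof_dw,
                              function(k) 0.54 + 0.46 * cos(pi * k / ko64)),
            0.02)
  prof_e <- empirical_density(trajectory_samples(tiny_spec("e_concept", 64)),
                              FOV, 64)
  expect_lt(density_rms_error(prof_e, function(k) 1 / k), 0.02)
})

test_that("a full Cartesian grid grids to a flat profile", {
  kx <- rep((-8:7) / FOV, 16)
  ky <- rep((-8:7) / FOV, each = 16)
  prof <- empirical_density(data.frame(kx = kx, ky = ky), FOV, 16)
  g <- prof$grid
  # interior radii: the kernel footprint tapers near the square's edge
  sel <- g$k <= 5 / FOV
  expect_lt(diff(range(g$density[sel])) / mean(g$density[sel]), 0.02)
  expect_error(empirical_density(data.frame(), FOV, 16), "empty")
})

test_that("density profiles round-trip through CSV + JSON sidecar", {
  tr <- trajectory_samples(tiny_spec("dw_concept", matrix = 16))
  prof <- empirical_density(tr, FOV, 16)
  path <- file.path(withr::local_tempdir(), "dens.csv")
  write_density_profile(prof, path)
  back <- read_density_profile(path)
  expect_equal(back$grid$density, prof$grid$density, tolerance = 1e-12)
  expect_equal(back$k_max, prof$k_max, tolerance = 1e-9)
  kk <- seq(0.2, 0.8, by = 0.1) * prof$k_max
  expect_equal(back$fun(kk), prof$fun(kk), tolerance = 1e-9)
})
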