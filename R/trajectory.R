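## Concentric-circle trajectory geometry: circle radii for the equidistant
## (e-CONCEPT) and density-weighted (DW-CONCEPT) schemes, the radial
## Nyquist circle counts, temporal interleaving, acoustic validation and
## scan-time accounting.
##
## Radial conventions (calibrated once against the published minimum
## circle counts; see the methods vignette): the outermost circle of both
## schemes sits at k_out = (matrix - 1) / (2 FOV) -- for e-CONCEPT this is
## simply the (matrix/2)-th circle of the (i - 1/2)/FOV ladder -- and the
## density-weighted radii are the radius map evaluated on the half-offset
## grid k_i = (i - 1/2) k_out / (N - 1/2), whose last node lands exactly on
## k_out.

#' Outermost circle radius for a given matrix and field of view
#'
#' @param matrix Matrix size (voxels per side, even).
#' @param fov Field of view, m.
#' @return k-space radius of the outermost circle, 1/m.
#' @export
k_outer <- function(matrix, fov) (matrix - 1) / (2 * fov)

#' Gradient hardware limits
#'
#' @param g_max Maximum gradient amplitude, mT/m.
#' @param slew_max Maximum slew rate, mT/m/ms.
#' @param forbidden_bands List of `c(lo, hi)` acoustic frequency intervals
#'   (Hz) that the gradient fundamental must avoid.  Defaults to the
#'   mechanical resonances 550 +/- 50 and 1100 +/- 150 Hz of a typical 7 T
#'   whole-body gradient coil.
#' @param avoided_band Additional deliberately avoided interval, Hz.
#' @return An object of class `gradient_limits`.
#' @export
gradient_limits <- function(g_max = 40, slew_max = 200,
                            forbidden_bands = list(c(500, 600), c(950, 1250)),
                            avoided_band = c(950, 1250)) {
  stopifnot(g_max > 0, slew_max > 0)
  for (b in forbidden_bands) stopifnot(length(b) == 2L, b[1] < b[2])
  structure(list(g_max = g_max, slew_max = slew_max,
                 forbidden_bands = forbidden_bands,
                 avoided_band = avoided_band),
            class = "gradient_limits")
}

## Internal: density-weighted radii on the calibrated half-offset grid.
dw_map_radii <- function(matrix, fov, n_circles,
                         alpha = HAMMING_ALPHA, beta = HAMMING_BETA) {
  ko <- k_outer(matrix, fov)
  map <- solve_radius_map(ks_filter("hamming", ko, alpha, beta))
  ki <- (seq_len(n_circles) - 0.5) / (n_circles - 0.5) * ko
  map$forward(ki)
}

#' Circle radii for a concentric-circle scheme
#'
#' For `e_concept` the radii increase with the constant step `1/FOV`
#' starting at `1/(2 FOV)`: \eqn{K_i = (i - 1/2)/FOV}.  For `dw_concept`
#' the radii follow the Hamming-density radius map on the calibrated
#' half-offset grid; the innermost circle is anchored at `1/(2 FOV)`
#' (`anchor_first = TRUE`, the default), matching the acquisition scheme,
#' which affects only the k-space center, not the density over the
#' verification window.
#'
#' @param scheme `"e_concept"` or `"dw_concept"`.
#' @param matrix Matrix size.
#' @param fov Field of view, m.
#' @param n_circles Number of circles; defaults to
#'   [nyquist_min_circles()].  A count below the Nyquist minimum triggers a
#'   warning (undersampling), not an error.
#' @param anchor_first Anchor the innermost DW circle at `1/(2 FOV)`.
#' @return Strictly increasing vector of circle radii, 1/m.
#' @export
circle_radii <- function(scheme = c("e_concept", "dw_concept"),
                         matrix, fov, n_circles = NULL,
                         anchor_first = TRUE) {
  scheme <- match.arg(scheme)
  n_min <- nyquist_min_circles(scheme, matrix, fov)
  if (is.null(n_circles)) n_circles <- n_min
  if (n_circles < 1) stopf("n_circles must be >= 1")
  if (n_circles < n_min)
    warning(sprintf("%d circles is below the radial Nyquist minimum %d for %s",
                    n_circles, n_min, scheme), call. = FALSE)
  if (scheme == "e_concept") {
    (seq_len(n_circles) - 0.5) / fov
  } else {
    r <- dw_map_radii(matrix, fov, n_circles)
    if (anchor_first) r[1] <- 1 / (2 * fov)
    r
  }
}

#' Minimum number of circles under the radial Nyquist criterion
#'
#' The smallest circle count whose radii (on the scheme's calibrated
#' discretization, without the innermost-circle anchor) satisfy the radial
#' Nyquist criterion: adjacent-radius spacing at most `1/FOV` everywhere,
#' counting the gap from the k-space origin to the first circle, with the
#' outermost circle reaching `k_outer(matrix, fov)`.  For equidistant
#' circles this is the closed form `matrix/2`; for the density-weighted
#' scheme the first (innermost) gap of the radius map binds.
#'
#' @inheritParams circle_radii
#' @param filter Optional Hamming [ks_filter] overriding the default
#'   coefficients for the density-weighted map.
#' @return Integer circle count.
#' @export
nyquist_min_circles <- function(scheme = c("e_concept", "dw_concept"),
                                matrix, fov, filter = NULL) {
  scheme <- match.arg(scheme)
  if (matrix < 8 || matrix %% 2 != 0)
    stopf("matrix must be even and >= 8")
  if (scheme == "e_concept") return(as.integer(matrix %/% 2L))
  alpha <- if (is.null(filter)) HAMMING_ALPHA else filter$alpha
  beta <- if (is.null(filter)) HAMMING_BETA else filter$beta
  ko <- k_outer(matrix, fov)
  ok <- function(n) {
    r <- dw_map_radii(matrix, fov, n, alpha, beta)
    max(diff(c(0, r))) <= 1 / fov * (1 + 1e-9) &&
      r[length(r)] >= ko * (1 - 1e-9)
  }
  ## the binding innermost gap shrinks ~ 1/sqrt(N): bracket then bisect
  lo <- 2L
  hi <- max(4L, matrix)
  while (!ok(hi)) { lo <- hi; hi <- hi * 2L }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (ok(mid)) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

#' Temporal interleave schedule
#'
#' Interleave `j` (0-based) delays its ADC train by `j * t_rev /
#' n_interleaves`; merging the trains yields an effective spectral dwell of
#' `t_rev / n_interleaves`, i.e. a spectral bandwidth of `n_interleaves /
#' t_rev`, at the cost of one extra excitation per circle per interleave.
#' Each excitation acquires `n_fid_points / n_interleaves` revolutions of
#' one circle (padded up if not divisible).
#'
#' @param n_fid_points Spectral points after merging.
#' @param n_interleaves Number of temporal interleaves (>= 1).
#' @param t_rev Revolution time, s.
#' @return List with per-interleave `delays` (s), `revolutions_per_excitation`,
#'   `spectral_dwell` (s), `spectral_bandwidth` (Hz), and the merged
#'   timestamp grid `merged_times` (s, relative to the readout start).
#' @export
interleave_schedule <- function(n_fid_points, n_interleaves, t_rev) {
  if (n_interleaves < 1) stopf("n_interleaves must be >= 1")
  stopifnot(t_rev > 0, n_fid_points >= 1)
  n_pad <- ceiling(n_fid_points / n_interleaves) * n_interleaves
  dwell <- t_rev / n_interleaves
  list(
    delays = (seq_len(n_interleaves) - 1) * dwell,
    revolutions_per_excitation = n_pad %/% n_interleaves,
    n_fid_points = n_pad,
    spectral_dwell = dwell,
    spectral_bandwidth = n_interleaves / t_rev,
    merged_times = (seq_len(n_pad) - 1) * dwell
  )
}

#' Check the gradient fundamental against forbidden acoustic bands
#'
#' The concentric-circle readout drives both gradient axes sinusoidally at
#' the revolution frequency `1/t_rev`; mechanical gradient-coil resonances
#' make some frequency bands unsafe.  Fails if the fundamental falls inside
#' any forbidden band or the deliberately avoided range.
#'
#' @param t_rev Revolution time, s.
#' @param n_interleaves Temporal interleaves (reported for context).
#' @param limits A [gradient_limits].
#' @return List with `pass` (logical), `fundamental_hz`, and the
#'   `offending_band` (or NULL).
#' @export
validate_acoustics <- function(t_rev, n_interleaves = 1,
                               limits = gradient_limits()) {
  stopifnot(t_rev > 0)
  f0 <- 1 / t_rev
  bands <- c(limits$forbidden_bands, list(limits$avoided_band))
  for (b in bands) {
    if (f0 >= b[1] && f0 <= b[2])
      return(list(pass = FALSE, fundamental_hz = f0, offending_band = b))
  }
  list(pass = TRUE, fundamental_hz = f0, offending_band = NULL)
}

#' Full acquisition geometry and timing for a concentric-circle protocol
#'
#' Bundles the field of view, matrix, circle radii, revolution timing,
#' interleaving and spectral dimension into a validated trajectory
#' specification.  The revolution time is `samples_per_rev * adc_dwell`
#' exactly (integer samples per revolution); the default samples per
#' revolution is the azimuthal Nyquist count `pi * matrix` times an
#' oversampling factor of 1.34, reproducing 270 samples at matrix 64 with
#' a 250 kHz ADC.
#'
#' @param scheme `"e_concept"` or `"dw_concept"`.
#' @param matrix Matrix size.
#' @param fov Field of view, m.
#' @param n_circles Circle count (default: radial Nyquist minimum).
#' @param n_interleaves Temporal interleaves.
#' @param n_fid_points Spectral points (merged).
#' @param adc_dwell ADC dwell time, s.
#' @param samples_per_rev Samples per revolution; default as above.
#' @param tr Repetition time, s.
#' @param acq_delay Acquisition delay after excitation, s.
#' @param azimuthal_oversampling Oversampling factor on `pi * matrix`.
#' @param limits A [gradient_limits]; when `samples_per_rev` is not given,
#'   the revolution is lengthened beyond the azimuthal-Nyquist default if
#'   the outermost circle would otherwise exceed the slew-rate limit
#'   (which happens for small matrices at a 250 kHz ADC).
#' @param anchor_first See [circle_radii()].
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(scheme = c("dw_concept", "e_concept"),
                            matrix = 64, fov = 0.22,
                            n_circles = NULL, n_interleaves = 3,
                            n_fid_points = 819, adc_dwell = 4e-6,
                            samples_per_rev = NULL,
                            tr = 0.6, acq_delay = 1.3e-3,
                            azimuthal_oversampling = 1.34,
                            limits = gradient_limits(),
                            anchor_first = TRUE) {
  scheme <- match.arg(scheme)
  if (is.null(samples_per_rev)) {
    samples_per_rev <- ceiling(pi * matrix * azimuthal_oversampling)
    ## slew-feasible minimum revolution time for the outermost circle:
    ## slew = 4 pi^2 k_out / (gamma t_rev^2) <= slew_max (1% safety)
    t_min <- sqrt(4 * pi^2 * k_outer(matrix, fov) /
                    (GAMMA_BAR * limits$slew_max)) * 1.01
    samples_per_rev <- max(samples_per_rev, ceiling(t_min / adc_dwell))
  }
  if (samples_per_rev < ceiling(pi * matrix))
    stopf("samples_per_rev %d below the azimuthal Nyquist count %d",
          samples_per_rev, ceiling(pi * matrix))
  t_rev <- samples_per_rev * adc_dwell
  radii <- circle_radii(scheme, matrix, fov, n_circles,
                        anchor_first = anchor_first)
  if (any(diff(radii) <= 0) || radii[1] <= 0)
    stopf("circle radii must be strictly increasing and positive")
  il <- interleave_schedule(n_fid_points, n_interleaves, t_rev)
  structure(list(
    scheme = scheme, matrix = matrix, fov = fov,
    radii = radii, n_circles = length(radii),
    n_interleaves = n_interleaves, t_rev = t_rev,
    adc_dwell = adc_dwell, samples_per_rev = samples_per_rev,
    n_fid_points = il$n_fid_points, tr = tr, acq_delay = acq_delay,
    interleaves = il, k_outer = k_outer(matrix, fov)
  ), class = "trajectory_spec")
}

#' @export
print.trajectory_spec <- function(x, ...) {
  cat(sprintf(
    "<trajectory_spec> %s | matrix %d, FOV %.0f mm | %d circles (outermost %.1f 1/m)\n",
    x$scheme, x$matrix, x$fov * 1e3, x$n_circles, max(x$radii)))
  cat(sprintf(
    "  t_rev %.4g ms (%d samples @ %.2g us), %d interleaves -> SBW %.0f Hz, %d FID points\n",
    x$t_rev * 1e3, x$samples_per_rev, x$adc_dwell * 1e6, x$n_interleaves,
    x$interleaves$spectral_bandwidth, x$n_fid_points))
  invisible(x)
}

#' Total scan duration of a protocol
#'
#' `duration = (n_circles * n_interleaves * averages + prescan_excitations)
#' * TR`, itemized per component.  Prescans (noise decorrelation, coil
#' combination weights, preparation shots) are timing items only.
#'
#' @param spec A [trajectory_spec].
#' @param averages Number of averages.
#' @param prescans Extra prescan excitations.
#' @return List with `total_s` and an itemized breakdown.
#' @export
scan_time <- function(spec, averages = 1, prescans = 0) {
  stopifnot(inherits(spec, "trajectory_spec"))
  enc <- spec$n_circles * spec$n_interleaves * averages
  list(total_s = (enc + prescans) * spec$tr,
       encoding_excitations = enc,
       prescan_excitations = prescans,
       tr_s = spec$tr)
}

#' Sample table of a trajectory (one row per spatial sample)
#'
#' Expands a [trajectory_spec] into per-sample k-space positions, azimuth
#' indices, circle indices and intra-revolution time offsets `tau`.  Each
#' (circle, azimuth) position carries the full merged FID dimension; the
#' timestamp of FID point `m` at that position is
#' `acq_delay + m * spectral_dwell + tau`.
#'
#' @param spec A [trajectory_spec].
#' @return data.frame with columns `kx`, `ky`, `circle`, `azimuth`, `tau`.
#' @export
trajectory_samples <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  S <- spec$samples_per_rev
  az <- 0:(S - 1)
  phi <- 2 * pi * az / S
  do.call(rbind, lapply(seq_along(spec$radii), function(i) {
    r <- spec$radii[i]
    data.frame(kx = r * cos(phi), ky = r * sin(phi),
               circle = i, azimuth = az, tau = az * spec$adc_dwell)
  }))
}

#' Export a trajectory design to CSV + JSON header
#'
#' Writes one steady-state revolution per circle (time, gradients, k-space
#' position, ADC flag, circle and interleave index) together with a JSON
#' header carrying FOV, matrix, timing, the gyromagnetic ratio and the full
#' radius list; the schema is re-importable with [read_trajectory()].
#'
#' @param spec A [trajectory_spec].
#' @param path CSV output path (header goes to `<path>.json`).
#' @param limits A [gradient_limits] used to synthesize the waveforms.
#' @export
write_trajectory <- function(spec, path, limits = gradient_limits()) {
  stopifnot(inherits(spec, "trajectory_spec"))
  rows <- lapply(seq_along(spec$radii), function(i) {
    wf <- design_circle_waveform(spec$radii[i], spec$t_rev, spec$adc_dwell,
                                 limits, n_revolutions = 1)
    n <- length(wf$time)
    data.frame(time_s = wf$time, gx_mT_per_m = wf$gx, gy_mT_per_m = wf$gy,
               kx_per_m = wf$kx, ky_per_m = wf$ky,
               adc_flag = as.integer(seq_len(n) >= wf$adc_start),
               circle_index = i, interleave_index = 0L)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  hdr <- list(scheme = spec$scheme, fov_m = spec$fov, matrix = spec$matrix,
              t_rev_s = spec$t_rev, adc_dwell_s = spec$adc_dwell,
              n_interleaves = spec$n_interleaves,
              n_fid_points = spec$n_fid_points, tr_s = spec$tr,
              acq_delay_s = spec$acq_delay,
              samples_per_rev = spec$samples_per_rev,
              gamma_bar_hz_per_t = GAMMA_BAR, radii_per_m = spec$radii)
  jsonlite::write_json(hdr, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- trajectory_spec(
    scheme = hdr$scheme, matrix = hdr$matrix, fov = hdr$fov_m,
    n_circles = length(hdr$radii_per_m),
    n_interleaves = hdr$n_interleaves, n_fid_points = hdr$n_fid_points,
    adc_dwell = hdr$adc_dwell_s, samples_per_rev = hdr$samples_per_rev,
    tr = hdr$tr_s, acq_delay = hdr$acq_delay_s)
  spec$radii <- hdr$radii_per_m
  spec$waveform_table <- read.csv(path)
  spec
}
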