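## Intra-circle linear phase correction.
##
## Samples along one revolution are measured at different times; for
## off-resonant spins this smears the spatial encoding.  Each sample's
## merged FID series is uniformly sampled at the effective spectral dwell
## with a constant offset tau (its azimuthal position within the
## revolution), so a frequency-dependent phase ramp exp(-2 pi i f tau)
## applied in the spectral domain refers every sample of a revolution to
## the common revolution start.

#' Linear phase correction for intra-revolution acquisition-time offsets
#'
#' Transforms each sample's FID to the spectral domain, applies
#' \eqn{e^{-2\pi i f \tau}} with \eqn{\tau} the sample's intra-revolution
#' time offset, and transforms back.  On-resonance signals are unchanged;
#' off-resonance signals regain their correct spatial phase and lose the
#' azimuthal blur.
#'
#' @param samples A [sampled_kspace] with a FID dimension.
#' @return The corrected [sampled_kspace] (flag `phase_corrected` set).
#' @export
linear_phase_correct <- function(samples) {
  stopifnot(inherits(samples, "sampled_kspace"))
  if (is.null(samples$data) || ncol(samples$data) < 1L)
    stopf("samples carry no FID dimension")
  nf <- ncol(samples$data)
  f <- fft_freqs(nf, samples$spectral_dwell)
  sp <- mvfft(t(samples$data))                       # fid x samples
  sp <- sp * exp(-2i * pi * outer(f, samples$traj$tau))
  samples$data <- t(mvfft(sp, inverse = TRUE)) / nf
  samples$phase_corrected <- TRUE
  samples
}
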