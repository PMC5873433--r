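## Small internal numeric helpers shared across modules.

## Centered <-> FFT-order index permutation for even length n.
fft_shift_idx <- function(n) c((n / 2 + 1):n, 1:(n / 2))

## 2-D fftshift (even dims only, which is all this package uses).
fftshift2 <- function(m) {
  m[fft_shift_idx(nrow(m)), fft_shift_idx(ncol(m)), drop = FALSE]
}

## Inverse 2-D DFT with centered conventions: input and output both have
## their DC cell at index n/2 + 1 (1-based).  Unnormalized: computes
## img(p) = sum_q F(q) exp(+2i pi q p / n) over centered indices q, p.
ifft2_centered <- function(m) {
  fftshift2(fft(fftshift2(m), inverse = TRUE))
}

## FFT frequencies (Hz) for n points at dwell dt, in FFT bin order.
fft_freqs <- function(n, dt) {
  k <- 0:(n - 1)
  k[k >= n / 2] <- k[k >= n / 2] - n
  k / (n * dt)
}

## Relative root-mean-square difference between two numeric vectors/arrays,
## normalized by the RMS of the reference.
rel_rms <- function(x, ref) {
  sqrt(mean(Mod(x - ref)^2)) / sqrt(mean(Mod(ref)^2))
}

## Least-squares scale fit of `x` onto `ref` (real vectors): the factor s
## minimizing ||s * x - ref||^2.
ls_scale <- function(x, ref) sum(ref * x) / sum(x * x)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
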