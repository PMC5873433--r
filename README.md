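# dwconcept

Design and desk-scale evaluation of **density-weighted concentric-circle
k-space trajectories** for FID-MRSI (free-induction-decay magnetic
resonance spectroscopic imaging).

High-resolution MRSI at ultra-high field suffers from lipid signal
bleeding out of the scalp into the brain, because the point spread
function (PSF) of an unfiltered k-space has strong sidelobes.
Retrospective Hamming filtering fixes the PSF but throws away SNR.
Concentric-circle spatial-spectral readouts (CONCEPT) can instead spend
their *acquisition time* across k-space in proportion to the filter, so
the Hamming weighting is acquired, not imposed. This package implements
the full chain for that idea:

* **SNR-efficiency theory.** For an acquisition density
  \(\rho_{Acq}\) and target density \(\rho_{Target}\), the noise variance
  is \(\sigma^2 = \int \rho_{Target}^2/\rho_{Acq}\, d^2k\) and the SNR
  relative to uniform sampling of equal duration is
  \(\sqrt{\sigma^2_{Uniform}/\sigma^2_{Acq}}\), maximized when
  \(\rho_{Acq}=\rho_{Target}\). For the radial Hamming target
  \(H(k)=0.54+0.46\cos(\pi k/k_{max})\) this evaluates to **125.2%** for a
  density-matched acquisition, **114.9%** for the natural \(1/k\) density
  of equidistant circles, and **109.0%** for their quotient.
* **Radius map.** Circle radii \(K(k)\) that realize the Hamming density
  solve the separable ODE \(K'\,K\,H(K)=c_1\) with \(K(0)=0\),
  \(K(k_{max})=k_{max}\); the package solves it in closed form
  (antiderivative + monotone root finding) and derives the minimum circle
  counts under the radial Nyquist criterion (16/32/64 equidistant,
  44/177/714 density-weighted at matrices 32/64/128).
* **Waveforms.** Slew- and amplitude-checked gradient waveforms per
  circle (radial prewinder, tangential spin-up, constant-angular-velocity
  revolutions, ramp-down), temporal interleaving (3 interleaves at a
  1.08 ms revolution give a 2778 Hz spectral bandwidth), and acoustic
  validation against forbidden resonance bands.
* **Reconstruction.** Modified Pipe–Menon density compensation directly
  onto the Hamming target (no retrospective filter), Kaiser–Bessel
  gridding (width 3, overgridding 2) as a sparse operator, post-gridding
  density correction, intra-circle linear phase correction, deapodized
  FFT and crop, spectral transforms, PSF metrics.
* **Simulation.** Analytic phantoms (closed-form disk/ellipse/Gaussian
  transforms — no inverse crime), noisy acquisition with true per-sample
  timestamps, pseudo-replica SNR maps in the spectral domain, and the
  end-to-end experiments that verify the theory numbers and the
  localization behavior.

## Worked example

```r
library(dwconcept)

spec <- trajectory_spec("dw_concept", matrix = 64, fov = 0.22)
spec
#> <trajectory_spec> dw_concept | matrix 64, FOV 220 mm | 177 circles (outermost 143.2 1/m)
#>   t_rev 1.08 ms (270 samples @ 4 us), 3 interleaves -> SBW 2778 Hz, 819 FID points
```

177 circles is the radial Nyquist minimum for a Hamming-density 64 × 64
protocol (vs. 32 equidistant circles); at TR 600 ms and 3 temporal
interleaves, 192 circles take 345.6 s of encoding.

```r
round(snr_theory_table() * 100, 1)
#>   hamming_vs_uniform inverse_k_vs_uniform hamming_vs_inverse_k
#>                125.2                114.9                109.0
```

The density-matched acquisition buys 25.2% SNR over uniform sampling of
the same duration and 9.0% over equidistant circles. The outermost
circle is hardware-friendly:

```r
wf <- design_circle_waveform(max(spec$radii), spec$t_rev, spec$adc_dwell)
#> |g| = 19.6 mT/m, slew = 114 mT/m/ms        (limits: 40 mT/m, 200 mT/m/ms)
```

Gridding unit-valued samples of the designed trajectory (no density
compensation) recovers the Hamming profile — the density really is
acquired:

```r
prof <- empirical_density(trajectory_samples(
  trajectory_spec("dw_concept", 64, 0.22, n_interleaves = 1, n_fid_points = 1)),
  fov = 0.22, matrix = 64)
ko <- k_outer(64, 0.22)
density_rms_error(prof, function(k) 0.54 + 0.46 * cos(pi * k / ko))
#> 0.0013          # 0.13% RMS over [0.1, 0.95] k_max
```

and the chain PSF is the Hamming-apodized disk transform (FWHM 1.95
voxels, first sidelobe 0.5% of the peak).

End-to-end Monte-Carlo verification (256 noise replicas per protocol,
32 × 32 desk protocol, ~1 min):

```r
ex <- experiment_snr_ratios(n_replicas = 256, seed = 1)
ex$ratios
#>  dw_vs_epe   e_vs_epe     dw_vs_e
#>      1.234      1.124       1.098   # theory: 1.252 / 1.149 / 1.090
```

## Command line

```sh
Rscript exec/dwconcept design --scheme dw --matrix 64 --nyquist --out-dir out/
Rscript exec/dwconcept snr-theory
Rscript exec/dwconcept experiment --experiment snr-ratios --seed 1 --out-dir out/
```

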