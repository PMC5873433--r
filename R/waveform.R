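## Gradient waveform synthesis for one concentric circle: prewinder
## (radial move-out, then tangential acceleration), steady constant-
## angular-velocity revolutions, and a slew-limited ramp-down.
##
## The waveform is generated by differencing an analytic k-space path on
## the ADC raster, so the discrete cumulative sum gamma_bar * g * dt
## reproduces the commanded path exactly by construction.

#' Design the gradient waveform for one circle
#'
#' Steady-state circumnavigation of a circle of radius `r` (1/m) in time
#' `t_rev` requires the gradient amplitude \eqn{|g| = 2\pi r / (\bar\gamma
#' t_{rev})} and slew rate \eqn{|g| \cdot 2\pi / t_{rev}}; both are checked
#' against the hardware limits before any waveform is built.  The
#' prewinder first moves radially outward with a smooth (raised-cosine)
#' lobe at 95% of the slew limit, then accelerates tangentially to orbital
#' angular velocity; samples acquired before the steady phase are
#' discarded, and the ADC begins at the first steady sample.  After the
#' revolutions the gradients are ramped linearly to zero.
#'
#' @param radius Circle radius, 1/m.
#' @param t_rev Revolution time, s.
#' @param adc_dwell Gradient/ADC raster time, s.
#' @param limits A [gradient_limits].
#' @param n_revolutions Steady revolutions to generate (one per FID point
#'   per excitation).
#' @return An object of class `circle_waveform`: `time` (s), `gx`, `gy`
#'   (mT/m), `kx`, `ky` (1/m, cumulative path), `adc_start` (index of the
#'   first steady sample), `g_steady` (mT/m), `slew_steady` (mT/m/ms), and
#'   the phase boundaries.
#' @export
design_circle_waveform <- function(radius, t_rev, adc_dwell,
                                   limits = gradient_limits(),
                                   n_revolutions = 1) {
  stopifnot(radius >= 0, t_rev > 0, adc_dwell > 0, n_revolutions >= 1)
  g_max <- limits$g_max * 1e-3        # T/m
  s_max <- limits$slew_max            # (mT/m/ms == T/m/s)
  omega <- 2 * pi / t_rev
  g_steady <- radius * omega / GAMMA_BAR            # T/m
  slew_steady <- g_steady * omega                   # T/m/s
  if (g_steady > g_max)
    stopf("infeasible radius: steady amplitude %.1f mT/m exceeds limit %.1f",
          g_steady * 1e3, limits$g_max)
  if (slew_steady > s_max)
    stopf("infeasible revolution time: steady slew %.1f mT/m/ms exceeds limit %.1f",
          slew_steady, limits$slew_max)

  s_pre <- 0.95 * s_max  # prewinder headroom below the hard limit
  ## phase A: radial raised-cosine move-out 0 -> radius
  ## rho(t) = r (1 - cos(pi t / T1)) / 2; peak |rho''| = r pi^2 / (2 T1^2)
  T1 <- if (radius > 0) {
    t_slew <- pi * sqrt(radius / (2 * GAMMA_BAR * s_pre))
    t_amp <- radius * pi / (2 * GAMMA_BAR * g_max)  # peak velocity cap
    max(t_slew, t_amp)
  } else 0
  ## phase B: tangential spin-up, theta'(t) = omega t / T2; the combined
  ## slew at the end is sqrt((r omega / T2)^2 + (r omega^2)^2) / gamma
  T2 <- if (radius > 0) {
    margin <- (GAMMA_BAR * s_max * 0.999)^2 - (radius * omega^2)^2
    t_need <- if (margin > 0) radius * omega / sqrt(margin) else Inf
    max(t_rev / 4, t_need)
  } else 0
  if (!is.finite(T2))
    stopf("infeasible revolution time: no slew headroom for the prewinder")

  dt <- adc_dwell
  n1 <- ceiling(T1 / dt)
  n2 <- ceiling(T2 / dt)
  T1 <- n1 * dt
  T2 <- n2 * dt
  n3 <- round(n_revolutions * t_rev / dt)

  kpath <- function(t) {
    rho <- ifelse(t < T1, radius * (1 - cos(pi * pmin(t, T1) / T1)) / 2, radius)
    if (T1 == 0) rho <- rep(radius, length(t))
    th <- ifelse(t < T1, 0,
          ifelse(t < T1 + T2,
                 0.5 * omega * (t - T1)^2 / T2,
                 0.5 * omega * T2 + omega * (t - T1 - T2)))
    cbind(rho * cos(th), rho * sin(th))
  }
  t_end <- T1 + T2 + n3 * dt
  tt <- seq(0, t_end, by = dt)
  k <- kpath(tt)
  g <- diff(k) / (GAMMA_BAR * dt)                    # T/m between samples
  ## ramp-down: linear to zero at the prewinder slew rate
  g_end <- g[nrow(g), ]
  n4 <- ceiling(sqrt(sum(g_end^2)) / (s_pre * dt))
  ramp <- if (n4 > 0) outer(1 - seq_len(n4) / n4, g_end) else NULL
  g <- rbind(g, ramp)
  k_full <- rbind(c(0, 0), apply(g * GAMMA_BAR * dt, 2, cumsum))
  g <- rbind(g, c(0, 0))  # gradients end at zero
  n <- nrow(g)
  time <- seq(0, by = dt, length.out = n)

  slew <- sqrt(rowSums(diff(g)^2)) / dt
  if (any(slew > s_max * (1 + 1e-6)))
    stopf("internal error: discrete slew %.1f exceeds limit %.1f",
          max(slew), s_max)
  amp <- sqrt(rowSums(g^2))
  if (any(amp > g_max * (1 + 1e-6)))
    stopf("internal error: discrete amplitude exceeds limit")

  structure(list(
    time = time, gx = g[, 1] * 1e3, gy = g[, 2] * 1e3,
    kx = k_full[, 1], ky = k_full[, 2],
    adc_start = n1 + n2 + 1L, n_adc = n3,
    g_steady = g_steady * 1e3, slew_steady = slew_steady,
    phases = c(prewind_radial = T1, prewind_tangential = T2,
               steady = n3 * dt, rampdown = (n - 1) * dt - T1 - T2 - n3 * dt)
  ), class = "circle_waveform")
}
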