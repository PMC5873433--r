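## Circle radius map for density-weighted concentric circles.
##
## Writing the circle radii as K(k), a monotone redistribution of an
## equidistant radial coordinate k, the Jacobian of the polar transform
## (kx, ky) = (K cos phi, K sin phi) is J = K dK/dk, and demanding that the
## sampling density equal the radial Hamming filter H(K) yields the
## separable ODE
##     K'(k) K(k) H(K(k)) = c1,    K(0) = 0,  K(k_max) = k_max.
## Separation of variables gives the closed-form inverse k(K) through the
## antiderivative F(K) = int_0^K u H(u) du; the forward map K(k) is then
## obtained by monotone root finding (exact to tolerance, with none of the
## truncation artifacts of a high-order series inversion near k_max).

## Antiderivative F(K) = int_0^K u * (alpha + beta cos(pi u / kmax)) du.
hamming_moment <- function(K, k_max, alpha = HAMMING_ALPHA, beta = HAMMING_BETA) {
  x <- K / k_max
  k_max^2 * (alpha * x^2 / 2 +
             beta * ((cos(pi * x) - 1) / pi^2 + x * sin(pi * x) / pi))
}

#' Solve the radius-map ODE for a density-weighted circle distribution
#'
#' Solves \eqn{K'(k) K(k) H(K(k)) = c_1} with boundary conditions
#' \eqn{K(0) = 0}, \eqn{K(k_{max}) = k_{max}} by separation of variables.
#' The separation constant is \eqn{c_1 = F(k_{max}) / k_{max}} with
#' \eqn{F(K) = \int_0^K u H(u)\,du}, the inverse map is the closed form
#' \eqn{k(K) = F(K) / c_1}, and the forward map \eqn{K(k)} is evaluated by
#' bracketing root finding to `|dK| <= 1e-10 k_max`.
#'
#' @param filter A Hamming-kind [ks_filter] (requires `alpha > beta` so the
#'   integrand stays positive and the map is strictly monotone).  A
#'   uniform-kind filter is also accepted and yields the closed form
#'   \eqn{K(k) = k_{max}\sqrt{k / k_{max}}}.
#' @return An object of class `radius_map` with fields `forward` (K of k),
#'   `inverse` (k of K), `c1`, `k_max`, and `jacobian` (K dK/dk).
#' @export
solve_radius_map <- function(filter) {
  stopifnot(inherits(filter, "ks_filter"))
  if (!filter$kind %in% c("hamming", "uniform"))
    stopf("radius map requires a hamming- or uniform-kind target filter")
  k_max <- filter$k_max
  alpha <- if (filter$kind == "uniform") 1 else filter$alpha
  beta <- if (filter$kind == "uniform") 0 else filter$beta
  if (alpha <= beta)
    stopf("non-monotone integrand: requires alpha > beta")
  Ffun <- function(K) hamming_moment(K, k_max, alpha, beta)
  c1 <- Ffun(k_max) / k_max
  inverse <- function(K) {
    if (any(K < -1e-12 | K > k_max * (1 + 1e-12)))
      stopf("K outside [0, k_max]")
    Ffun(pmin(pmax(K, 0), k_max)) / c1
  }
  forward <- function(k) {
    if (any(k < -1e-12 | k > k_max * (1 + 1e-12)))
      stopf("k outside [0, k_max]")
    vapply(pmin(pmax(k, 0), k_max), function(kk) {
      if (kk <= 0) return(0)
      if (kk >= k_max) return(k_max)
      uniroot(function(K) Ffun(K) - c1 * kk, c(0, k_max),
              tol = 1e-10 * k_max)$root
    }, numeric(1))
  }
  H <- function(K) alpha + beta * cos(pi * K / k_max)
  jacobian <- function(k) c1 / H(forward(k))  # J = K dK/dk = c1 / H(K)
  structure(list(forward = forward, inverse = inverse, c1 = c1,
                 k_max = k_max, alpha = alpha, beta = beta,
                 jacobian = jacobian,
                 method = "separation of variables + bracketing root finder"),
            class = "radius_map")
}

## Residual of the ODE at interior points (for validation/tests):
## |K'(k) K(k) H(K(k)) - c1| with K' from a central difference.
radius_map_residual <- function(map, k, h = 1e-6) {
  stopifnot(inherits(map, "radius_map"))
  h <- h * map$k_max
  Kp <- (map$forward(k + h) - map$forward(k - h)) / (2 * h)
  K <- map$forward(k)
  H <- map$alpha + map$beta * cos(pi * K / map$k_max)
  abs(Kp * K * H - map$c1)
}
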