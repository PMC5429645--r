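#' Non-linear pre-puncture spring coefficients
#'
#' While the proxy is pinned to a tissue surface and the tip advances, the
#' rendered force follows a second-degree polynomial in the proxy-tip
#' displacement `d`: `f(d) = a2 d^2 + a1 d + a0`. `a0` is the force level
#' at which the ramp starts (the sustained force of the tissue just
#' passed, or 0 coming from air), `a1 in [0, k]` is a free design slope,
#' and `a2 = k (k - a1) / |T_N - a0|` is chosen so that the polynomial
#' reaches the cut threshold `T_N` at exactly the displacement
#' `(T_N - a0) / k` where the plain linear spring of stiffness `k` would
#' — the non-linear spring punctures at the same displacement as the
#' linear one, whatever `a1`. `a1 = k` recovers the linear spring
#' (`a2 = 0`); an infinite threshold (bone) also degenerates to the
#' linear spring, which then just ramps until the device force limit.
#'
#' @param T_N Cut-force threshold of the surface being pressed, N.
#' @param a0 Start force level, N (sustained force before the surface).
#' @param k Tissue stiffness, N/mm.
#' @param a1 Design slope in N/mm, within `[0, k]`.
#' @return A list with elements `a0`, `a1`, `a2`.
#' @examples
#' # skin entered from air: T_N = 0.7, k = 0.8
#' cs <- spring_coeffs(0.7, 0, 0.8, a1 = 0)
#' spring_force(0.7 / 0.8, cs)  # reaches T_N at the linear displacement
#' @export
spring_coeffs <- function(T_N, a0, k, a1 = k / 2) {
  if (a1 < 0 || a1 > k) {
    abort(sprintf("`a1` must lie in [0, k] = [0, %g], got %g", k, a1))
  }
  if (a0 < 0) abort("`a0` must be >= 0")
  a2 <- if (!is.finite(T_N) || T_N == a0) 0 else k * (k - a1) / abs(T_N - a0)
  if (!is.finite(T_N)) a1 <- k  # impenetrable: plain Hooke ramp at slope k
  list(a0 = as.numeric(a0), a1 = as.numeric(a1), a2 = as.numeric(a2))
}

#' Evaluate the pre-puncture spring force
#'
#' @param d Proxy-tip displacement(s), mm (>= 0).
#' @param coeffs Coefficients from [spring_coeffs()].
#' @param device_max Force ceiling of the haptic device, N.
#' @return Force(s) in N, clamped to `device_max`.
#' @export
spring_force <- function(d, coeffs, device_max = Inf) {
  if (any(d < 0)) abort("displacement `d` must be >= 0")
  pmin(coeffs$a2 * d^2 + coeffs$a1 * d + coeffs$a0, device_max)
}

#' Displacement at which a surface is punctured
#'
#' Closed form shared by the linear and non-linear springs: the cut
#' threshold `T_N` is reached at `d* = (T_N - a0) / k`.
#'
#' @inheritParams spring_coeffs
#' @return Displacement in mm (`Inf` for impenetrable tissue).
#' @export
puncture_displacement <- function(T_N, a0, k) {
  if (!is.finite(T_N)) return(Inf)
  (T_N - a0) / k
}
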