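# Baumann-Fayer analytical donor survival for homogeneous acceptor planes.

# Single-plane exponent integral
#   S_h(t) = int_0^inf [1 - exp(-(t/tau) (R0^2 / (rho^2 + h^2))^3)] 2 pi rho drho
# evaluated with the substitution u = rho^2 + h^2, which turns it into
#   pi * int_{h^2}^inf [1 - exp(-(t/tau) R0^6 / u^3)] du.
# For h = 0 this has the closed form pi R0^2 Gamma(2/3) (t/tau)^(1/3).
bf_plane_exponent <- function(t_over_tau, r0, h, rel_tol = 1e-8) {
  if (t_over_tau <= 0) return(0)
  cc <- t_over_tau * r0^6
  f <- function(u) 1 - exp(-cc / u^3)
  # split at the scale u* = cc^(1/3) where the exponent is O(1)
  ustar <- max(cc^(1 / 3), h^2)
  i1 <- integrate(f, h^2, ustar, rel.tol = rel_tol,
                  subdivisions = 200L)$value
  i2 <- integrate(f, ustar, Inf, rel.tol = rel_tol,
                  subdivisions = 200L)$value
  pi * (i1 + i2)
}

#' Baumann-Fayer donor survival for homogeneous acceptor planes
#'
#' Analytical FRET-only donor survival when acceptors are distributed
#' homogeneously (no domains) on one or more planes parallel to the donor
#' plane: `G(t) = exp(-c_A * sum_p S_hp(t))` where `S_h(t)` integrates the
#' transfer probability over a plane at offset `h`. With a single in-plane
#' acceptor population (`h = 0`) the exponent reduces to the classical
#' two-dimensional `t^(1/3)` law, `c_A pi R0^2 Gamma(2/3) (t/tau)^(1/3)`.
#'
#' @param time Time grid (ns).
#' @param photo A [photophysics()] object; `c_a` is the per-plane acceptor
#'   density (nm^-2).
#' @param plane_offsets Distances (nm) of the acceptor planes from the donor
#'   plane; `c(0, h)` models same-leaflet plus cross-leaflet acceptors.
#' @param rel_tol Relative tolerance of the quadrature.
#' @return A `survival_curve` tibble (`time`, `g`).
#' @examples
#' ph <- photophysics(r0 = 5, amplitudes = 1, lifetimes = 3, c_a = 0.001)
#' bf_survival(seq(0, 30, 0.5), ph)
#' @export
bf_survival <- function(time, photo, plane_offsets = c(0, 4),
                        rel_tol = 1e-8) {
  stopifnot(inherits(photo, "photophysics"))
  if (any(plane_offsets < 0)) abort("plane offsets must be non-negative.")
  if (any(time < 0)) abort("`time` must be non-negative.")
  s_tot <- bf_total_exponent(time, photo, plane_offsets, rel_tol)
  out <- tibble::tibble(time = time, g = exp(-photo$c_a * s_tot))
  structure(out, class = c("survival_curve", class(out)),
            model = "baumann-fayer", plane_offsets = plane_offsets)
}

# Sum of per-plane exponent integrals over the time grid (without c_A).
bf_total_exponent <- function(time, photo, plane_offsets, rel_tol = 1e-8) {
  vapply(time, function(t) {
    sum(vapply(plane_offsets,
               function(h) bf_plane_exponent(t / photo$tau_bar, photo$r0, h,
                                             rel_tol),
               numeric(1)))
  }, numeric(1))
}

#' Calibrate the acceptor surface density from a homogeneous-bilayer decay
#'
#' Fits the Baumann-Fayer composed decay
#' `F(t) = s * I(t) * exp(-c_A * S(t))` to a measured donor+acceptor decay
#' from a homogeneous bilayer, with `I(t)` the intrinsic donor model and `s`
#' an analytic least-squares scale factor. The only free shape parameter is
#' `c_A`, profiled on a weighted chi-squared (`weights = max(counts, 1)`,
#' the Poisson approximation); the confidence interval is the
#' `delta chi^2 = 1` profile interval.
#'
#' @param decay_da Measured donor+acceptor [compose_decay()]-style histogram
#'   from a bilayer without domains.
#' @param photo A [photophysics()] object supplying `R0` and the intrinsic
#'   decay (its `c_a` is ignored).
#' @param plane_offsets Acceptor plane offsets (nm), as in [bf_survival()].
#' @param upper Upper bound of the density search (nm^-2).
#' @return A one-row tibble: `c_a`, `conf_low`, `conf_high`, `chi2_red`,
#'   `converged`.
#' @export
fit_acceptor_density <- function(decay_da, photo, plane_offsets = c(0, 4),
                                 upper = 0.1) {
  if (all(decay_da$counts == 0)) abort("decay is identically zero.")
  s_tot <- bf_total_exponent(decay_da$time, photo, plane_offsets)
  intr <- intrinsic_intensity(photo, decay_da$time)
  d <- decay_da$counts
  w <- pmax(d, 1)
  chi2 <- function(c_a) {
    m <- intr * exp(-c_a * s_tot)
    s <- sum(d * m / w) / sum(m^2 / w)
    sum((d - s * m)^2 / w)
  }
  opt <- optimize(chi2, c(0, upper), tol = 1e-10)
  # refine near the optimum (optimize's interval can be coarse at the edge)
  lo <- max(0, opt$minimum * 0.5)
  hi <- min(upper, max(opt$minimum * 2, 1e-6))
  opt <- optimize(chi2, c(lo, hi), tol = 1e-12)
  c_hat <- opt$minimum
  chi_min <- opt$objective
  dof <- length(d) - 2L  # c_A and the scale factor
  target <- chi_min + 1
  ci <- c(NA_real_, NA_real_)
  f <- function(x) chi2(x) - target
  if (f(0) > 0) {
    ci[1] <- uniroot(f, c(0, c_hat), tol = 1e-10)$root
  } else ci[1] <- 0
  if (f(upper) > 0) {
    ci[2] <- uniroot(f, c(c_hat, upper), tol = 1e-10)$root
  }
  converged <- is.finite(c_hat) && c_hat < upper * 0.999
  if (!converged)
    warn("acceptor-density fit hit the search bound; result flagged.")
  tibble::tibble(c_a = c_hat, conf_low = ci[1], conf_high = ci[2],
                 chi2_red = chi_min / dof, converged = converged)
}
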