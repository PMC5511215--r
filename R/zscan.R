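#' Two-dimensional diffusion autocorrelation model
#'
#' Normalized FCS autocorrelation for free two-dimensional (membrane)
#' diffusion: `G(lag) = (1/N) / (1 + lag / tau_diff)`, with `N` the mean
#' particle number in the detection area and `tau_diff` the dwell time.
#'
#' @param lag Lag time(s) (s).
#' @param n_particles Mean particle number, > 0.
#' @param tau_diff Diffusion dwell time (s), > 0.
#' @return Autocorrelation value(s).
#' @examples
#' acf_2d(6e-3, n_particles = 10, tau_diff = 2e-3)
#' @export
acf_2d <- function(lag, n_particles, tau_diff) {
  check_number(n_particles, "n_particles", lower = 1e-12)
  check_number(tau_diff, "tau_diff", lower = 1e-12)
  if (any(lag < 0)) abort("`lag` must be non-negative.")
  (1 / n_particles) / (1 + lag / tau_diff)
}

#' Fit the 2D diffusion model to one autocorrelation curve
#'
#' Weighted least-squares fit of [acf_2d()] to a measured curve; weights are
#' uniform unless per-lag standard deviations are supplied.
#'
#' @param curve A tibble with columns `lag` (s) and `g`; optionally `sd`.
#' @return A one-row tibble: `n_particles`, `tau_diff`, their standard
#'   errors, and `converged`.
#' @export
fit_acf <- function(curve) {
  if (is.unsorted(curve$lag, strictly = TRUE))
    abort("`lag` must be strictly increasing.")
  w <- if ("sd" %in% names(curve) && all(curve$sd > 0)) 1 / curve$sd^2
       else rep(1, nrow(curve))
  start <- list(n_particles = 1 / max(curve$g[1], 1e-9),
                tau_diff = curve$lag[max(which(curve$g >= curve$g[1] / 2))])
  fit <- try(minpack.lm::nlsLM(
    g ~ (1 / n_particles) / (1 + lag / tau_diff),
    data = curve, start = start, weights = w,
    lower = c(1e-9, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(tibble::tibble(n_particles = NA_real_, tau_diff = NA_real_,
                          se_n = NA_real_, se_tau = NA_real_,
                          converged = FALSE))
  }
  co <- summary(fit)$coefficients
  tibble::tibble(n_particles = co["n_particles", 1],
                 tau_diff = co["tau_diff", 1],
                 se_n = co["n_particles", 2], se_tau = co["tau_diff", 2],
                 converged = TRUE)
}

#' z-scan FCS diffusion-law fit
#'
#' Fits the z-scan diffusion law
#' `tau_diff(z) = (w0^2 / 4D) * (1 + (lambda (z - z0) / (pi w0^2 n))^2)`
#' to per-position dwell times, returning the diffusion coefficient `D`, the
#' beam waist `w0` and the focus offset `z0`. The dwell-time parabola is
#' symmetric about `z0`, where it attains its minimum `w0^2 / (4 D)`.
#'
#' @param series A tibble with columns `z` (nm, relative position) and `tau`
#'   (dwell time, ms); at least 5 positions spanning the waist.
#' @param wavelength Excitation wavelength lambda (nm).
#' @param ref_index Refractive index of the medium.
#' @return A `zscan_fit` object; `tidy()` gives parameter estimates with
#'   standard errors and 95% confidence bounds, `glance()` a one-row summary
#'   (`d` in um^2/s, `w0` and `z0` in nm), `autoplot()` the fitted parabola.
#'   A fit whose minimum falls outside the scanned range is flagged
#'   (`extrapolated`).
#' @examples
#' z <- seq(-1425, 1425, by = 150)
#' tau <- (250^2 / (4 * 5) / 1e6) * (1 + (470 * z / (pi * 250^2 * 1.33))^2) * 1e3
#' zscan_diffusion_fit(tibble::tibble(z = z, tau = tau))
#' @export
zscan_diffusion_fit <- function(series, wavelength = 470, ref_index = 1.33) {
  if (nrow(series) < 5) abort("at least 5 z positions are required.")
  if (any(series$tau <= 0)) abort("dwell times must be positive.")
  # starting values from the quadratic regression tau ~ z + z^2:
  # tau(z) = tau0 [1 + (lambda (z - z0) / (pi w0^2 n))^2]
  qf <- stats::lm(tau ~ z + I(z^2), data = series)
  cf <- coef(qf)
  if (is.na(cf[3]) || cf[3] <= 0) {
    z0_start <- series$z[which.min(series$tau)]
    tau0 <- max(min(series$tau), 1e-6)
    w0_start <- 250
  } else {
    z0_start <- -cf[2] / (2 * cf[3])
    tau0 <- max(cf[1] - cf[2]^2 / (4 * cf[3]), 1e-6)
    w0_start <- sqrt(wavelength / (pi * ref_index) * sqrt(tau0 / cf[3]))
  }
  d_start <- w0_start^2 * 1e-3 / (4 * tau0)  # nm^2, ms -> um^2/s
  model <- function(p, z) {
    (p[["w0"]]^2 / (4 * p[["d"]]) * 1e-3) *
      (1 + (wavelength * (z - p[["z0"]]) /
              (pi * p[["w0"]]^2 * ref_index))^2)
  }
  fit <- minpack.lm::nls.lm(
    par = c(d = unname(d_start), w0 = unname(w0_start),
            z0 = unname(z0_start)),
    fn = function(p) series$tau - model(p, series$z),
    lower = c(1e-6, 10, min(series$z) - 5000),
    upper = c(1e4, 5000, max(series$z) + 5000),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  co <- fit$par
  dof <- nrow(series) - 3L
  sigma <- sqrt(fit$deviance / dof)
  se <- tryCatch(sqrt(diag(sigma^2 * solve(fit$hessian))),
                 error = function(e) rep(NA_real_, 3))
  extrapolated <- co[["z0"]] < min(series$z) || co[["z0"]] > max(series$z)
  if (extrapolated)
    warn("fitted focus position lies outside the scanned range (extrapolation).")
  structure(
    list(par = co, se = setNames(se, names(co)), sigma = sigma, model = model,
         series = series, wavelength = wavelength, ref_index = ref_index,
         extrapolated = extrapolated, converged = fit$info %in% 1:4),
    class = "zscan_fit"
  )
}

#' @export
print.zscan_fit <- function(x, ...) {
  cat(sprintf("<zscan_fit> D = %.3g um^2/s, w0 = %.3g nm, z0 = %.3g nm%s\n",
              x$par[["d"]], x$par[["w0"]], x$par[["z0"]],
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' @export
coef.zscan_fit <- function(object, ...) object$par

#' @export
tidy.zscan_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$par),
    estimate = unname(x$par),
    std_error = unname(x$se),
    conf_low = unname(x$par - 1.96 * x$se),
    conf_high = unname(x$par + 1.96 * x$se)
  )
}

#' @export
glance.zscan_fit <- function(x, ...) {
  tibble::tibble(d = x$par[["d"]], w0 = x$par[["w0"]], z0 = x$par[["z0"]],
                 tau_min = x$par[["w0"]]^2 / (4 * x$par[["d"]]) * 1e-3,
                 sigma = x$sigma, converged = x$converged,
                 extrapolated = x$extrapolated)
}

#' @rdname zscan_diffusion_fit
#' @param object A `zscan_fit`.
#' @param ... Ignored.
#' @export
autoplot.zscan_fit <- function(object, ...) {
  zz <- seq(min(object$series$z), max(object$series$z), length.out = 200)
  pred <- tibble::tibble(z = zz, tau = object$model(object$par, zz))
  ggplot2::ggplot(object$series, ggplot2::aes(.data$z, .data$tau)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::labs(x = "z (nm)", y = "tau_diff (ms)")
}

#' Compare diffusion coefficients between two sample groups
#'
#' Welch's two-sample unequal-variance t-test on per-vesicle diffusion
#' coefficients; differences with p below the threshold (default 0.1) are
#' flagged significant.
#'
#' @param group_a,group_b Numeric vectors of diffusion coefficients
#'   (um^2/s), at least 3 values each.
#' @param alpha Significance threshold on the p-value.
#' @return A one-row tibble: group means, their difference, `p_value`,
#'   `significant`.
#' @examples
#' compare_diffusion(c(5.0, 5.1, 4.9, 5.0), c(4.3, 4.4, 4.2, 4.3))
#' @export
compare_diffusion <- function(group_a, group_b, alpha = 0.1) {
  if (length(group_a) < 3 || length(group_b) < 3)
    abort("each group needs at least 3 values.")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0)
    abort("both groups have zero variance; the t-test is undefined.")
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  tibble::tibble(
    mean_a = mean(group_a), mean_b = mean(group_b),
    difference = mean(group_a) - mean(group_b),
    p_value = tt$p.value,
    significant = tt$p.value < alpha
  )
}
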