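#' Cole-Cole / Debye dispersion parameters
#'
#' Container for the single-pole Cole-Cole description of a dispersive
#' dielectric,
#' \deqn{\epsilon_r(\omega) = \epsilon_{r\infty} +
#'   \frac{\epsilon_{rs} - \epsilon_{r\infty}}{1 + (j\omega\tau)^{1-\alpha}} -
#'   \frac{j\sigma}{\epsilon_0 \omega},}
#' evaluated under the \eqn{e^{+j\omega t}} time convention so that lossy
#' media have a negative imaginary part. `alpha = 0` is the Debye model; a
#' dispersionless material is expressed with `eps_s == eps_inf` (then `tau`
#' may be 0).
#'
#' @param eps_inf Relative permittivity at infinite frequency (>= 1).
#' @param eps_s Static relative permittivity (defaults to `eps_inf`).
#' @param sigma Static conductivity in S/m (>= 0).
#' @param tau Relaxation time in seconds (> 0 unless the material is
#'   dispersionless, i.e. `eps_s == eps_inf`).
#' @param alpha Cole-Cole broadening parameter in `[0, 1)`.
#' @param name Optional material label.
#' @return An object of class `dispersion_params`.
#' @export
#' @examples
#' ptfe <- dispersion_params(2.1, name = "PTFE")
#' complex_permittivity(ptfe, 30e9)
dispersion_params <- function(eps_inf, eps_s = eps_inf, sigma = 0, tau = 0,
                              alpha = 0, name = NULL) {
  stopifnot(is.numeric(eps_inf), length(eps_inf) == 1L, is.finite(eps_inf),
            is.numeric(eps_s), length(eps_s) == 1L, is.finite(eps_s),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (eps_inf < 1) stop("eps_inf must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  if (eps_s != eps_inf && tau <= 0)
    stop("tau must be > 0 for a dispersive material (eps_s != eps_inf)")
  if (tau < 0) stop("tau must be >= 0")
  structure(list(eps_inf = eps_inf, eps_s = eps_s, sigma = sigma,
                 tau = tau, alpha = alpha, name = name),
            class = "dispersion_params")
}

#' @export
print.dispersion_params <- function(x, ...) {
  nm <- if (is.null(x$name)) "<unnamed>" else x$name
  cat(sprintf(
    "Dispersion model %s: eps_inf=%.4g eps_s=%.4g sigma=%.4g S/m tau=%.4g ps alpha=%.4g\n",
    nm, x$eps_inf, x$eps_s, x$sigma, x$tau * 1e12, x$alpha))
  invisible(x)
}

#' Vacuum (air) reference medium
#' @return `dispersion_params` with relative permittivity 1.
#' @export
vacuum_medium <- function() dispersion_params(1, name = "vacuum")

#' Complex relative permittivity of a dispersive material
#'
#' Evaluates the Cole-Cole model of a [dispersion_params] object at
#' frequencies `f`. The conduction term \eqn{-j\sigma/(\epsilon_0\omega)}
#' makes the imaginary part negative for passive media
#' (\eqn{e^{+j\omega t}} convention). The fractional power
#' \eqn{(j\omega\tau)^{1-\alpha}} uses the principal branch; for
#' \eqn{\omega\tau > 0} the argument stays away from the branch cut.
#'
#' @param params A [dispersion_params] object.
#' @param f Frequency in Hz (vectorized, all > 0 and finite).
#' @return Complex relative permittivity, same length as `f`.
#' @export
#' @examples
#' gel <- dispersion_params(4.62, 42.5, 1.02, 11.8e-12, 0.075, "gel")
#' complex_permittivity(gel, c(21e9, 42e9))
complex_permittivity <- function(params, f) {
  stopifnot(inherits(params, "dispersion_params"))
  if (!is.numeric(f) || length(f) == 0L || any(!is.finite(f)) || any(f <= 0))
    stop("f must be finite and > 0")
  w <- 2 * pi * f
  disp <- if (params$eps_s == params$eps_inf) 0 + 0i else
    (params$eps_s - params$eps_inf) /
      (1 + (1i * w * params$tau)^(1 - params$alpha))
  cond <- if (params$sigma == 0) 0 + 0i else
    -1i * params$sigma / (.phys$eps0 * w)
  rep_len(params$eps_inf + disp + cond, length(f))
}

#' Loss tangent of a dispersive material
#'
#' `-Im(eps)/Re(eps)`, non-negative for passive media under the adopted sign
#' convention.
#'
#' @inheritParams complex_permittivity
#' @return Numeric loss tangent, same length as `f`.
#' @export
loss_tangent <- function(params, f) {
  e <- complex_permittivity(params, f)
  if (any(Re(e) <= 0))
    stop("degenerate medium: real part of permittivity must be > 0")
  -Im(e) / Re(e)
}

#' Fit a Debye model to an arbitrary dispersion model over a band
#'
#' Finds Debye parameters (`alpha = 0`) minimizing the summed squared
#' complex-permittivity deviation from `source` on a logarithmically spaced
#' frequency grid, with real and imaginary parts weighted equally. Used to
#' obtain per-band Debye surrogates of a Cole-Cole material.
#'
#' @param source A [dispersion_params] object.
#' @param band Numeric length-2 frequency interval in Hz, within (0, 110 GHz].
#' @param n_points Number of sample frequencies (>= 4), default 50.
#' @return A `dispersion_params` object with `alpha = 0`; attributes
#'   `residual_max_rel` (worst relative complex deviation over the band) and
#'   `residual_rms_rel` record fit quality.
#' @export
#' @examples
#' gel <- dispersion_params(4.62, 42.5, 1.02, 11.8e-12, 0.075, "gel")
#' deb <- fit_debye_to_dispersion(gel, c(21e9, 42e9))
#' attr(deb, "residual_max_rel")
fit_debye_to_dispersion <- function(source, band, n_points = 50) {
  stopifnot(inherits(source, "dispersion_params"))
  if (length(band) != 2L || any(!is.finite(band)) || any(band <= 0) ||
      band[2] > 110e9)
    stop("band must be a finite interval within (0, 110 GHz]")
  if (band[2] <= band[1]) stop("degenerate band: need band[2] > band[1]")
  if (n_points < 4) stop("n_points must be >= 4")
  f <- exp(seq(log(band[1]), log(band[2]), length.out = n_points))
  target <- complex_permittivity(source, f)
  scl <- mean(Mod(target))

  ## parameterization: eps_inf, d_eps = eps_s - eps_inf, sigma, tau (ps)
  resid <- function(p) {
    m <- dispersion_params(max(p[1], 1), max(p[1], 1) + max(p[2], 0),
                           max(p[3], 0), max(p[4], 1e-4) * 1e-12)
    e <- complex_permittivity(m, f)
    c(Re(e - target), Im(e - target)) / scl
  }
  init <- c(source$eps_inf, max(source$eps_s - source$eps_inf, 0),
            source$sigma, max(source$tau * 1e12, 1e-3))
  fit <- minpack.lm::nls.lm(
    par = init, fn = resid,
    lower = c(1, 0, 0, 1e-4), upper = c(1e3, 1e4, 1e3, 1e6),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  if (fit$info == 0 || any(!is.finite(fit$par))) {
    e <- simpleError("Debye fit did not converge")
    e$last_par <- fit$par
    e$residual <- fit$deviance
    stop(e)
  }
  p <- fit$par
  out <- dispersion_params(p[1], p[1] + p[2], p[3], p[4] * 1e-12, 0,
                           name = paste0(source$name %||% "source", "_debye"))
  dev <- Mod(complex_permittivity(out, f) - target) / Mod(target)
  attr(out, "residual_max_rel") <- max(dev)
  attr(out, "residual_rms_rel") <- sqrt(mean(dev^2))
  attr(out, "band") <- band
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
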