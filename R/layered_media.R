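#' A single layer of a stratified medium
#'
#' @param material A [dispersion_params] object.
#' @param thickness Thickness in meters (> 0), or `Inf` for the terminal
#'   half-space.
#' @return An object of class `sw_layer`.
#' @export
layer <- function(material, thickness) {
  stopifnot(inherits(material, "dispersion_params"),
            is.numeric(thickness), length(thickness) == 1L)
  if (!(is.infinite(thickness) || thickness > 0))
    stop("thickness must be > 0 (finite) or Inf for the terminal half-space")
  structure(list(material = material, thickness = thickness),
            class = "sw_layer")
}

#' Stratified medium: ordered layers over a terminal half-space
#'
#' Layers are ordered from the illuminated surface inward; the last (and only
#' the last) layer must be the infinite terminal half-space.
#'
#' @param ... `sw_layer` objects, or a single list of them.
#' @param incident_medium [dispersion_params] of the incident half-space
#'   (default vacuum).
#' @param name Optional stack label.
#' @return An object of class `layer_stack`.
#' @export
#' @examples
#' d95 <- dispersion_params(2.98, 32.8, 6.94, 8.76e-12, name = "layer_d_p95")
#' sc <- dispersion_params(2.96, 4.46, 0, 6.9e-12, name = "sc_thin")
#' skin <- layer_stack(layer(sc, 20e-6), layer(d95, Inf))
#' reflectance_db(skin, 15e9)
layer_stack <- function(..., incident_medium = vacuum_medium(), name = NULL) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1L]], "sw_layer"))
    layers <- layers[[1L]]
  if (length(layers) == 0L) stop("stack must contain at least one layer")
  if (!all(vapply(layers, inherits, logical(1), "sw_layer")))
    stop("all stack elements must be sw_layer objects")
  thick <- vapply(layers, `[[`, numeric(1), "thickness")
  if (sum(is.infinite(thick)) != 1L || !is.infinite(thick[length(thick)]))
    stop("stack must contain exactly one infinite layer, and it must be last")
  stopifnot(inherits(incident_medium, "dispersion_params"))
  structure(list(layers = layers, incident_medium = incident_medium,
                 name = name),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("Layer stack %s (%d layers):\n", x$name %||% "<unnamed>",
              length(x$layers)))
  for (ly in x$layers) {
    d <- if (is.infinite(ly$thickness)) "half-space" else
      sprintf("%.4g um", ly$thickness * 1e6)
    cat(sprintf("  %-14s %s\n", ly$material$name %||% "<material>", d))
  }
  invisible(x)
}

## Longitudinal wavenumber kz = sqrt(k^2 - kt^2) on the branch with
## Im(kz) <= 0 (decay along +z under e^{+j omega t}); for lossless evanescent
## regions the principal square root lands on +j and is flipped.
.branch_kz <- function(k2, kt2) {
  kz <- sqrt(k2 - kt2)
  flip <- Im(kz) > 0 | (Im(kz) == 0 & Re(kz) < 0)
  kz[flip] <- -kz[flip]
  kz
}

## Stable tanh(gamma d) for Re(gamma d) >= 0.
.ctanh <- function(z) {
  e2 <- exp(-2 * z)
  (1 - e2) / (1 + e2)
}

## Input wave admittance of the layer sequence seen at its top surface, for
## transverse wavenumber kt (vectorized; w may be scalar or same length).
## eps_layers: list of complex permittivity vectors (scalar or length of kt).
.input_admittance <- function(eps_layers, d, w, kt, pol) {
  pol <- match.arg(pol, c("TE", "TM"))
  n <- length(eps_layers)
  mody <- function(eps, kz) if (pol == "TE") kz / (w * .phys$mu0) else
    w * .phys$eps0 * eps / kz
  k02 <- w^2 * .phys$mu0 * .phys$eps0
  kzN <- .branch_kz(k02 * eps_layers[[n]], kt^2)
  Y <- mody(eps_layers[[n]], kzN)
  if (n >= 2L) for (i in (n - 1L):1L) {
    kzi <- .branch_kz(k02 * eps_layers[[i]], kt^2)
    Yi <- mody(eps_layers[[i]], kzi)
    t <- .ctanh(1i * kzi * d[i])
    Y <- Yi * (Y + Yi * t) / (Yi + Y * t)
  }
  Y
}

#' Spectral input admittance of a stack at a transverse wavenumber
#'
#' Wave admittance of the layered medium seen from its surface for a plane
#' wave (propagating or evanescent) with transverse wavenumber `kt`, per
#' polarization. This is the layered-media response that the waveguide-probe
#' mode-matching solver integrates over the spectral plane; `kt` may be
#' complex.
#'
#' @param stack A [layer_stack] (the incident medium is not involved).
#' @param f Frequency in Hz (scalar).
#' @param kt Transverse wavenumber in rad/m (vectorized, may be complex).
#' @param pol `"TE"` or `"TM"`.
#' @return Complex admittance in siemens, same length as `kt`.
#' @export
stack_admittance <- function(stack, f, kt, pol = c("TE", "TM")) {
  stopifnot(inherits(stack, "layer_stack"), length(f) == 1L, is.finite(f),
            f > 0)
  pol <- match.arg(pol)
  eps <- lapply(stack$layers, function(ly) complex_permittivity(ly$material, f))
  d <- vapply(stack$layers, `[[`, numeric(1), "thickness")
  .input_admittance(eps, d, 2 * pi * f, kt, pol)
}

#' Analytic plane-wave reflection coefficient of a stratified medium
#'
#' Field reflection coefficient at the first interface of the stack, computed
#' by recursive impedance (admittance) transformation through the layers. At
#' normal incidence on a single interface from vacuum this reduces to the
#' Fresnel coefficient \eqn{(1-\sqrt{\epsilon})/(1+\sqrt{\epsilon})}; TE and
#' TM coincide at normal incidence.
#'
#' @param stack A [layer_stack].
#' @param f Frequency in Hz (vectorized).
#' @param theta Incidence angle in radians, `0 <= theta < pi/2` (default 0,
#'   normal incidence). Oblique incidence requires a lossless incident medium.
#' @param pol `"TE"` or `"TM"`.
#' @return Complex reflection coefficient, same length as `f`;
#'   `|Gamma| <= 1` for passive stacks.
#' @export
plane_wave_reflection <- function(stack, f, theta = 0, pol = c("TE", "TM")) {
  stopifnot(inherits(stack, "layer_stack"))
  pol <- match.arg(pol)
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 ||
      theta >= pi / 2)
    stop("theta must lie in [0, pi/2)")
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= 0))
    stop("f must be finite and > 0")
  w <- 2 * pi * f
  eps_inc <- complex_permittivity(stack$incident_medium, f)
  if (theta > 0 && any(abs(Im(eps_inc)) > 1e-12))
    stop("oblique incidence requires a lossless incident medium")
  kt <- w / .phys$c0 * sqrt(Re(eps_inc)) * sin(theta)
  eps <- lapply(stack$layers, function(ly) complex_permittivity(ly$material, f))
  d <- vapply(stack$layers, `[[`, numeric(1), "thickness")
  Yin <- .input_admittance(eps, d, w, kt, pol)
  kz0 <- .branch_kz(w^2 * .phys$mu0 * .phys$eps0 * eps_inc, kt^2)
  Yinc <- if (pol == "TE") kz0 / (w * .phys$mu0) else
    w * .phys$eps0 * eps_inc / kz0
  (Yinc - Yin) / (Yinc + Yin)
}

#' Plane-wave reflectance in dB
#'
#' `20 log10 |Gamma|` of [plane_wave_reflection] (equal to 10 log10 of the
#' power reflectance). Non-positive for passive stacks with a lossless
#' incident medium; a total null returns `-Inf`.
#'
#' @inheritParams plane_wave_reflection
#' @return Numeric dB values, same length as `f`.
#' @export
reflectance_db <- function(stack, f, theta = 0, pol = c("TE", "TM")) {
  20 * log10(Mod(plane_wave_reflection(stack, f, theta, pol)))
}

#' Fraction of incident power absorbed by a stratified medium
#'
#' `1 - |Gamma|^2`. With a lossless incident medium and a lossy terminal
#' half-space this is the fraction of the incident plane-wave power density
#' deposited in the stack, the quantity underlying absorbed-power-density
#' assessment.
#'
#' @inheritParams plane_wave_reflection
#' @return Numeric in `[0, 1]`, same length as `f`.
#' @export
absorbed_power_fraction <- function(stack, f, theta = 0,
                                    pol = c("TE", "TM")) {
  g <- plane_wave_reflection(stack, f, theta, pol)
  1 - Mod(g)^2
}
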