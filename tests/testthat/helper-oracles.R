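## Shared fixtures and independent oracles for the test suite.

# validation gel and coating (built in code, independent of the YAML fixture)
gel_params <- function() dispersion_params(4.62, 42.5, 1.02, 11.8e-12, 0.075,
                                           "gel")
ptfe_params <- function() dispersion_params(2.1, name = "PTFE")

# seeded random Debye medium
random_debye <- function() {
  dispersion_params(eps_inf = runif(1, 1, 10),
                    eps_s = runif(1, 10, 60),
                    sigma = runif(1, 0, 10),
                    tau = runif(1, 1, 20) * 1e-12)
}

# random passive stack with up to `max_layers` finite layers
random_stack <- function(max_layers = 4) {
  nl <- sample.int(max_layers, 1)
  lys <- lapply(seq_len(nl), function(i)
    layer(random_debye(), runif(1, 5e-6, 2e-3)))
  lys[[nl + 1L]] <- layer(random_debye(), Inf)
  layer_stack(lys)
}

## Independent transfer-matrix oracle for plane-wave reflection: 2x2 ABCD
## cascade per layer, entirely separate from the package's recursive
## admittance implementation.
tmm_reflection <- function(stack, f, theta = 0, pol = "TE") {
  ph <- phys_constants()
  w <- 2 * pi * f
  k02 <- w^2 * ph$mu0 * ph$eps0
  kz_branch <- function(k2, kt2) {
    kz <- sqrt(k2 - kt2)
    if (Im(kz) > 0 || (Im(kz) == 0 && Re(kz) < 0)) -kz else kz
  }
  eps_inc <- complex_permittivity(stack$incident_medium, f)
  kt <- w / ph$c0 * sqrt(Re(eps_inc)) * sin(theta)
  admit <- function(eps) {
    kz <- kz_branch(k02 * eps, kt^2)
    if (pol == "TE") kz / (w * ph$mu0) else w * ph$eps0 * eps / kz
  }
  M <- diag(2) + 0i
  lys <- stack$layers
  for (i in seq_len(length(lys) - 1L)) {
    eps <- complex_permittivity(lys[[i]]$material, f)
    kz <- kz_branch(k02 * eps, kt^2)
    Y <- admit(eps)
    ph_d <- kz * lys[[i]]$thickness
    M <- M %*% matrix(c(cos(ph_d), 1i * Y * sin(ph_d),
                        1i * sin(ph_d) / Y, cos(ph_d)), 2, 2)
  }
  YL <- admit(complex_permittivity(lys[[length(lys)]]$material, f))
  Yin <- (M[2, 1] + M[2, 2] * YL) / (M[1, 1] + M[1, 2] * YL)
  Y0 <- admit(eps_inc)
  (Y0 - Yin) / (Y0 + Yin)
}

# two-band fit target from the plane-wave forward model of a stack
planewave_target <- function(stack, n_per_band = 25) {
  fw42 <- seq(15.5e9, 27.5e9, length.out = n_per_band)
  fw28 <- seq(22e9, 42e9, length.out = n_per_band)
  fit_target(data.frame(
    probe = rep(c("WR42", "WR28"), each = n_per_band),
    frequency = c(fw42, fw28),
    s11_db = c(reflectance_db(stack, fw42), reflectance_db(stack, fw28))))
}

# thin-SC skin stack from registry materials
thin_skin_stack <- function(layer_d) {
  reg <- skin_registry()
  layer_stack(layer(reg$materials$sc_thin, 20e-6), layer(layer_d, Inf))
}
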