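## Physical constants (CODATA 2018). Kept in one place so that the plane-wave
## and mode-matching solvers are guaranteed to share the same values and the
## same e^{+j omega t} time convention (lossy media have Im(eps) <= 0).
.phys <- list(
  eps0 = 8.8541878128e-12,   # vacuum permittivity, F/m
  mu0  = 1.25663706212e-6    # vacuum permeability, H/m
)
.phys$c0   <- 1 / sqrt(.phys$eps0 * .phys$mu0)  # speed of light, m/s
.phys$eta0 <- sqrt(.phys$mu0 / .phys$eps0)      # free-space impedance, ohm

#' Physical constants used by the solvers
#'
#' Returns the constants table (CODATA 2018) shared by all electromagnetic
#' computations in the package: vacuum permittivity `eps0` (F/m), permeability
#' `mu0` (H/m), speed of light `c0` (m/s) and free-space wave impedance
#' `eta0` (ohm).
#'
#' @return A named list.
#' @export
#' @examples
#' phys_constants()$c0
phys_constants <- function() .phys
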