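## Model registry: YAML files describing dispersive materials and named
## layer stacks. File conventions: thickness d_um in micrometers (.inf for a
## terminal half-space), tau_ps in picoseconds; converted to SI here, at one
## boundary.

.registry_material_fields <- c("name", "d_um", "eps_inf", "eps_s",
                               "sigma_S_per_m", "tau_ps", "alpha")

#' Load a model registry of materials and layer stacks
#'
#' Reads one or more YAML files with `materials` (keys `name`, `d_um`,
#' `eps_inf`, `eps_s`, `sigma_S_per_m`, `tau_ps`, `alpha`) and optional
#' `stacks` (keys `name`, `layers`: material names ordered from the surface
#' inward). Every loaded material is validated through [dispersion_params]
#' and every stack through [layer_stack].
#'
#' @param paths Character vector of YAML file paths.
#' @return A list with `materials` (named list of [dispersion_params], each
#'   carrying a `d_um` attribute) and `stacks` (named list of [layer_stack]).
#' @export
load_model_registry <- function(paths) {
  mats <- list()
  stks_raw <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("registry file not found: ", p)
    doc <- yaml::read_yaml(p)
    for (m in doc$materials %||% list()) {
      miss <- setdiff(.registry_material_fields, names(m))
      if (length(miss))
        stop(sprintf("material entry in %s missing field(s): %s",
                     p, paste(miss, collapse = ", ")))
      if (m$name %in% names(mats))
        stop("duplicate material name: ", m$name)
      dp <- dispersion_params(m$eps_inf, m$eps_s, m$sigma_S_per_m,
                              m$tau_ps * 1e-12, m$alpha, name = m$name)
      attr(dp, "d_um") <- m$d_um
      mats[[m$name]] <- dp
    }
    for (s in doc$stacks %||% list()) {
      if (is.null(s$name) || is.null(s$layers))
        stop("stack entry in ", p, " must have 'name' and 'layers'")
      if (s$name %in% names(stks_raw))
        stop("duplicate stack name: ", s$name)
      stks_raw[[s$name]] <- s
    }
  }
  stks <- lapply(stks_raw, function(s) {
    lys <- lapply(s$layers, function(entry) {
      if (is.character(entry)) {
        mname <- entry; d_um <- NULL
      } else {
        mname <- entry$material; d_um <- entry$d_um
      }
      if (is.null(mats[[mname]]))
        stop("stack ", s$name, " references unknown material: ", mname)
      d_um <- d_um %||% attr(mats[[mname]], "d_um")
      d <- if (is.infinite(d_um)) Inf else d_um * 1e-6
      layer(mats[[mname]], d)
    })
    layer_stack(lys, name = s$name)
  })
  list(materials = mats, stacks = stks)
}

#' Shipped skin and validation model registry
#'
#' Loads the packaged registry: the tissue-simulating gel and PTFE coatings
#' used for probe validation, and the fitted two-layer skin models (Layer D
#' mean/68%/95% coverage; thin and thick stratum corneum).
#'
#' @return See [load_model_registry].
#' @export
#' @examples
#' reg <- skin_registry()
#' names(reg$stacks)
skin_registry <- function() {
  load_model_registry(system.file("extdata", "models.yaml",
                                  package = "skinwave", mustWork = TRUE))
}
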