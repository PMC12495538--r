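## Extraction of skin-layer dispersion parameters from dB reflection spectra
## by bounded least squares (Levenberg-Marquardt with box constraints,
## multi-start). The objective is the summed squared deviation of the
## dB-magnitude reflection between the forward model and the target, with
## equal weight on every frequency point across all bands.

#' Fit target: dB reflection spectra per probe band
#'
#' @param spectra Named list (names = probe labels, e.g. `"WR42"`) of
#'   [reflection_spectrum] objects, or a data frame with columns `probe`,
#'   `frequency`, `s11_db`.
#' @param percentile_label One of `"mean"`, `"mean-1sd"`, `"mean-2sd"`
#'   (records which coverage curve the target represents).
#' @return An object of class `fit_target`: a data frame with columns
#'   `probe`, `frequency`, `s11_db`.
#' @export
fit_target <- function(spectra, percentile_label = c("mean", "mean-1sd",
                                                     "mean-2sd")) {
  percentile_label <- match.arg(percentile_label)
  if (is.data.frame(spectra)) {
    stopifnot(all(c("probe", "frequency", "s11_db") %in% names(spectra)))
    df <- spectra[c("probe", "frequency", "s11_db")]
  } else {
    stopifnot(is.list(spectra), !is.null(names(spectra)))
    df <- do.call(rbind, lapply(names(spectra), function(p) {
      sp <- spectra[[p]]
      stopifnot(inherits(sp, "reflection_spectrum"))
      data.frame(probe = p, frequency = sp$frequency, s11_db = sp$s11_db)
    }))
  }
  if (any(!is.finite(df$s11_db))) stop("target dB values must be finite")
  ## overlapping band regions: deduplicate by nearest-grid merge
  df <- df[order(df$frequency, df$probe), ]
  rownames(df) <- NULL
  class(df) <- c("fit_target", "data.frame")
  attr(df, "percentile_label") <- percentile_label
  df
}

#' Fitter settings
#'
#' @param forward `"mm"` (mode-matching probe model, the production choice)
#'   or `"planewave"` (fast approximation using the analytic normal-incidence
#'   plane-wave solver; useful for smoke tests and large simulation studies).
#' @param n_starts Number of multi-start initial points (>= 1), default 8.
#' @param seed Seed for the start-point sampler.
#' @param mm MM solver settings used when `forward = "mm"`.
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @return An object of class `fit_settings`.
#' @export
fit_settings <- function(forward = c("mm", "planewave"), n_starts = 8,
                         seed = 1, mm = mm_settings(), max_iter = 200) {
  forward <- match.arg(forward)
  stopifnot(n_starts >= 1, max_iter >= 10)
  structure(list(forward = forward, n_starts = as.integer(n_starts),
                 seed = seed, mm = mm, max_iter = as.integer(max_iter)),
            class = "fit_settings")
}

## forward dB curve for a hypothesis stack on the target's frequency rows
.forward_db <- function(stack, target, wg_registry, settings) {
  if (settings$forward == "planewave")
    return(reflectance_db(stack, target$frequency))
  out <- numeric(nrow(target))
  for (p in unique(target$probe)) {
    idx <- target$probe == p
    wg <- wg_registry[[p]]
    if (is.null(wg)) stop("no waveguide registered for probe ", p)
    out[idx] <- 20 * log10(Mod(te10_reflection(wg, stack,
                                               target$frequency[idx],
                                               settings$mm)))
  }
  out
}

.default_wg_registry <- function() {
  nms <- wr_probe()
  stats::setNames(lapply(nms, wr_probe), nms)
}

## shared bounded LM multi-start driver.
## par space: natural-parameter list; mapping handled by make_stack(par).
.run_fit <- function(target, make_stack, lower, upper, inits, wg_registry,
                     settings) {
  resid_fn <- function(p) {
    .forward_db(make_stack(p), target, wg_registry, settings) - target$s11_db
  }
  best <- NULL
  for (k in seq_len(nrow(inits))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(inits[k, ]), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = settings$max_iter,
                           ftol = 1e-15, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("all fit starts failed")
  best
}

## seeded multi-start initial points within bounds (first row = init)
.make_starts <- function(init, lower, upper, n_starts, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  np <- length(init)
  extra <- matrix(stats::runif((n_starts - 1L) * np), ncol = np)
  extra <- sweep(sweep(extra, 2, upper - lower, `*`), 2, lower, `+`)
  rbind(matrix(init, nrow = 1), extra)
}

.fit_result <- function(best, params, thickness_m, target, make_stack,
                        wg_registry, settings, lower, upper, par_names) {
  res <- abs(best$fvec)
  active <- par_names[(best$par <= lower + 1e-9 * pmax(abs(lower), 1)) |
                        (best$par >= upper - 1e-9 * pmax(abs(upper), 1))]
  structure(list(
    params = params,
    thickness_m = thickness_m,
    residual_max_db = max(res),
    residual_rms_db = sqrt(mean(res^2)),
    n_iter = best$niter,
    converged = best$info %in% 1:4,
    bounds_active = active,
    deviance = best$deviance,
    percentile_label = attr(target, "percentile_label"),
    forward = settings$forward),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s forward, target %s): %s\n", x$forward,
              x$percentile_label %||% "?",
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  if (!is.na(x$thickness_m))
    cat(sprintf("  thickness: %.4g um\n", x$thickness_m * 1e6))
  cat(sprintf("  residual max %.3g dB, rms %.3g dB, %d iterations\n",
              x$residual_max_db, x$residual_rms_db, x$n_iter))
  if (length(x$bounds_active))
    cat("  active bounds:", paste(x$bounds_active, collapse = ", "), "\n")
  invisible(x)
}

.check_bounds <- function(lower, upper) {
  if (any(upper <= lower))
    stop("infeasible bounds: every upper bound must exceed its lower bound")
}

#' Fit the inner-skin layer (Layer D) to reflection spectra
#'
#' Recovers Debye parameters (`alpha = 0`) of the semi-infinite inner layer
#' beneath a fixed thin stratum-corneum layer by minimizing the summed
#' squared dB-magnitude deviation between the forward-modeled and target
#' reflection over all frequencies of all bands.
#'
#' @param target A [fit_target] covering at least two probe bands.
#' @param sc_layer Fixed surface [layer] (default: thin SC, 20 um, shipped
#'   literature parameters).
#' @param wg_registry Named list of [rect_waveguide] per probe label.
#' @param settings A [fit_settings] object.
#' @param init Optional [dispersion_params] starting point.
#' @param bounds Named list with elements `lower` and `upper`, each a named
#'   numeric vector over `eps_inf`, `eps_s`, `sigma`, `tau_ps`.
#' @return A `fit_result` with the fitted [dispersion_params], residual
#'   summaries, iteration count, convergence flag and any active bounds.
#' @export
fit_layer_d <- function(target, sc_layer = NULL,
                        wg_registry = .default_wg_registry(),
                        settings = fit_settings(), init = NULL,
                        bounds = NULL) {
  stopifnot(inherits(target, "fit_target"))
  if (length(unique(target$probe)) < 2L)
    stop("target must cover at least two probe bands")
  if (is.null(sc_layer)) {
    reg <- skin_registry()
    sc_layer <- layer(reg$materials$sc_thin, 20e-6)
  }
  stopifnot(inherits(sc_layer, "sw_layer"), is.finite(sc_layer$thickness))
  b <- .layerd_bounds(bounds)
  make_stack <- function(p) {
    mat <- dispersion_params(p[1], p[1] + p[2], p[3], max(p[4], 1e-4) * 1e-12)
    layer_stack(sc_layer, layer(mat, Inf))
  }
  if (is.null(init)) init <- dispersion_params(6, 40, 5, 8e-12)
  init_p <- pmin(pmax(c(init$eps_inf, init$eps_s - init$eps_inf, init$sigma,
                        init$tau * 1e12), b$lower), b$upper)
  starts <- .make_starts(init_p, b$lower, b$upper, settings$n_starts,
                         settings$seed)
  best <- .run_fit(target, make_stack, b$lower, b$upper, starts,
                   wg_registry, settings)
  p <- best$par
  params <- dispersion_params(p[1], p[1] + p[2], p[3], p[4] * 1e-12,
                              name = "layer_d_fit")
  .fit_result(best, params, NA_real_, target, make_stack, wg_registry,
              settings, b$lower, b$upper,
              c("eps_inf", "d_eps", "sigma", "tau_ps"))
}

## internal parameterization uses d_eps = eps_s - eps_inf >= 0 so the
## eps_s > eps_inf ordering is a box constraint.
.layerd_bounds <- function(bounds) {
  lower <- c(eps_inf = 1, eps_s = 2, sigma = 0, tau_ps = 1)
  upper <- c(eps_inf = 30, eps_s = 90, sigma = 30, tau_ps = 30)
  if (!is.null(bounds)) {
    lower[names(bounds$lower)] <- bounds$lower
    upper[names(bounds$upper)] <- bounds$upper
  }
  if (upper["eps_s"] <= lower["eps_inf"])
    stop("infeasible bounds: eps_s upper bound must exceed eps_inf lower bound")
  lo <- c(lower["eps_inf"], max(0, lower["eps_s"] - upper["eps_inf"]),
          lower["sigma"], lower["tau_ps"])
  hi <- c(upper["eps_inf"], upper["eps_s"] - lower["eps_inf"],
          upper["sigma"], upper["tau_ps"])
  names(lo) <- names(hi) <- c("eps_inf", "d_eps", "sigma", "tau_ps")
  .check_bounds(lo, hi)
  list(lower = lo, upper = hi)
}

#' Fit the thick stratum-corneum layer to reflection spectra
#'
#' As [fit_layer_d], but the free parameters are the stratum-corneum
#' thickness and its Debye parameters, while the inner layer is held fixed
#' (default: the mean-fit Layer D model).
#'
#' @inheritParams fit_layer_d
#' @param layer_d Fixed inner half-space [dispersion_params] (default the
#'   shipped mean Layer D model).
#' @param bounds Named list with `lower`/`upper` over `d_um`, `eps_inf`,
#'   `eps_s`, `sigma`, `tau_ps`; thickness defaults to `[50, 600]` um.
#' @return A `fit_result`; `thickness_m` holds the fitted SC thickness.
#' @export
fit_sc_thick <- function(target, layer_d = NULL,
                         wg_registry = .default_wg_registry(),
                         settings = fit_settings(), init = NULL,
                         bounds = NULL) {
  stopifnot(inherits(target, "fit_target"))
  if (is.null(layer_d)) layer_d <- skin_registry()$materials$layer_d_mean
  stopifnot(inherits(layer_d, "dispersion_params"))
  lower <- c(d_um = 50, eps_inf = 1, eps_s = 1.5, sigma = 0, tau_ps = 0.2)
  upper <- c(d_um = 600, eps_inf = 15, eps_s = 30, sigma = 10, tau_ps = 30)
  if (!is.null(bounds)) {
    lower[names(bounds$lower)] <- bounds$lower
    upper[names(bounds$upper)] <- bounds$upper
  }
  if (upper["eps_s"] <= lower["eps_inf"])
    stop("infeasible bounds: eps_s upper bound must exceed eps_inf lower bound")
  lo <- c(lower["d_um"], lower["eps_inf"],
          max(0, lower["eps_s"] - upper["eps_inf"]), lower["sigma"],
          lower["tau_ps"])
  hi <- c(upper["d_um"], upper["eps_inf"], upper["eps_s"] - lower["eps_inf"],
          upper["sigma"], upper["tau_ps"])
  names(lo) <- names(hi) <- c("d_um", "eps_inf", "d_eps", "sigma", "tau_ps")
  .check_bounds(lo, hi)
  make_stack <- function(p) {
    mat <- dispersion_params(p[2], p[2] + p[3], p[4], max(p[5], 1e-4) * 1e-12)
    layer_stack(layer(mat, p[1] * 1e-6), layer(layer_d, Inf))
  }
  if (is.null(init)) init <- list(d_um = 250,
                                  params = dispersion_params(3.5, 8.5, 0,
                                                             2e-12))
  init_p <- pmin(pmax(c(init$d_um, init$params$eps_inf,
                        init$params$eps_s - init$params$eps_inf,
                        init$params$sigma, init$params$tau * 1e12), lo), hi)
  starts <- .make_starts(init_p, lo, hi, settings$n_starts, settings$seed)
  best <- .run_fit(target, make_stack, lo, hi, starts, wg_registry, settings)
  p <- best$par
  params <- dispersion_params(p[2], p[2] + p[3], p[4], p[5] * 1e-12,
                              name = "sc_thick_fit")
  .fit_result(best, params, p[1] * 1e-6, target, make_stack, wg_registry,
              settings, lo, hi, c("d_um", "eps_inf", "d_eps", "sigma",
                                  "tau_ps"))
}
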