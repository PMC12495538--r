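fast <- function(n_starts = 8, seed = 3)
  fit_settings(forward = "planewave", n_starts = n_starts, seed = seed)

test_that("a target equal to the forward model of the init converges at once", {
  reg <- skin_registry()
  tgt <- planewave_target(reg$stacks$skin_thin_mean)
  fr <- fit_layer_d(tgt, settings = fast(n_starts = 1),
                    init = reg$materials$layer_d_mean)
  expect_true(fr$converged)
  expect_lt(fr$residual_max_db, 1e-10)
  expect_lte(fr$residual_rms_db, fr$residual_max_db)
})

test_that("noise-free synthetic targets are recovered to high fidelity", {
  reg <- skin_registry()
  tru <- reg$materials$layer_d_p68
  fr <- fit_layer_d(planewave_target(thin_skin_stack(tru)), settings = fast())
  expect_true(fr$converged)
  expect_lt(fr$residual_max_db, 1e-3)
  expect_equal(fr$params$eps_s, tru$eps_s, tolerance = 0.01)
  expect_equal(fr$params$eps_inf, tru$eps_inf, tolerance = 0.01)
  expect_equal(fr$params$tau, tru$tau, tolerance = 0.01)
})

test_that("thick-SC thickness is recovered and bound pinning is flagged", {
  reg <- skin_registry()
  sc <- reg$materials$sc_thick2
  stack <- layer_stack(layer(sc, 262e-6),
                       layer(reg$materials$layer_d_mean, Inf))
  tgt <- planewave_target(stack)
  fr <- fit_sc_thick(tgt, settings = fast())
  expect_true(fr$converged)
  expect_lt(abs(fr$thickness_m * 1e6 - 262), 10)
  expect_lt(fr$residual_max_db, 1e-3)

  # infeasible thickness window forces the optimum onto the bound
  frb <- fit_sc_thick(tgt, settings = fast(n_starts = 2),
                      bounds = list(lower = c(d_um = 50),
                                    upper = c(d_um = 150)))
  expect_true("d_um" %in% frb$bounds_active)
})

test_that("preconditions reject infeasible bounds and single-band targets", {
  reg <- skin_registry()
  tgt <- planewave_target(reg$stacks$skin_thin_mean)
  expect_error(
    fit_layer_d(tgt, settings = fast(),
                bounds = list(lower = c(eps_inf = 10),
                              upper = c(eps_s = 5))),
    "infeasible bounds")
  one_band <- fit_target(data.frame(probe = "WR42",
                                    frequency = seq(16e9, 27e9, 1e9),
                                    s11_db = rep(-3, 12)))
  expect_error(fit_layer_d(one_band, settings = fast()),
               "at least two probe bands")
  expect_error(fit_target(data.frame(probe = "WR42", frequency = 16e9,
                                     s11_db = NaN)), "finite")
})

test_that("the objective is invariant to frequency ordering of the target", {
  reg <- skin_registry()
  tgt <- planewave_target(thin_skin_stack(reg$materials$layer_d_p95))
  perm <- tgt[sample(seq_len(nrow(tgt))), ]
  tgt2 <- fit_target(as.data.frame(perm))
  f1 <- fit_layer_d(tgt, settings = fast(n_starts = 2))
  f2 <- fit_layer_d(tgt2, settings = fast(n_starts = 2))
  expect_equal(f1$params$eps_s, f2$params$eps_s, tolerance = 1e-6)
  expect_equal(f1$params$tau, f2$params$tau, tolerance = 1e-6)
})

test_that("recovery is robust to 0.1 dB measurement noise", {
  reg <- skin_registry()
  tru <- reg$materials$layer_d_mean
  clean <- planewave_target(thin_skin_stack(tru))
  set.seed(404)
  est <- replicate(20, {
    noisy <- clean
    noisy$s11_db <- noisy$s11_db + rnorm(nrow(noisy), 0, 0.1)
    fr <- fit_layer_d(fit_target(as.data.frame(noisy)),
                      settings = fast(n_starts = 2), init = tru)
    fr$params$eps_s
  })
  expect_lt(abs(mean(est) - tru$eps_s) / tru$eps_s, 0.05)
})
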