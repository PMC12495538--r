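test_that("Cole-Cole evaluation matches closed forms and a frozen oracle", {
  # dispersionless PTFE is purely real at any frequency
  expect_equal(complex_permittivity(ptfe_params(), c(1e9, 30e9, 110e9)),
               rep(2.1 + 0i, 3))

  # Debye at omega*tau = 1: real part is eps_inf + (eps_s - eps_inf)/2
  tau <- 8e-12
  deb <- dispersion_params(4, 40, 0, tau)
  f1 <- 1 / (2 * pi * tau)
  e <- complex_permittivity(deb, f1)
  expect_equal(Re(e), 4 + 36 / 2)
  expect_equal(Im(e), -36 / 2)

  # frozen value from independent arithmetic evaluation of the model
  d95 <- dispersion_params(2.98, 32.8, 6.94, 8.76e-12)
  expect_equal(complex_permittivity(d95, 15e9), 20.71277 - 22.95684i,
               tolerance = 1e-6)

  expect_error(complex_permittivity(deb, -1e9), "finite and > 0")
  expect_error(complex_permittivity(deb, NaN), "finite and > 0")
  expect_error(dispersion_params(0.5), "eps_inf")
  expect_error(dispersion_params(2, 40, 0, 0), "tau")
  expect_error(dispersion_params(2, 40, 0, 1e-12, alpha = 1), "alpha")
})

test_that("passivity, high-frequency limit and alpha-continuity hold", {
  set.seed(101)
  for (i in 1:25) {
    p <- dispersion_params(runif(1, 1, 10), runif(1, 10, 60), runif(1, 0, 5),
                           runif(1, 1, 20) * 1e-12, runif(1, 0, 0.3))
    f <- 10^runif(8, 8, 11.5)
    expect_true(all(Im(complex_permittivity(p, f)) <= 0))
    # high-frequency limit approaches eps_inf
    fhi <- 1e6 / (2 * pi * p$tau)
    expect_equal(Re(complex_permittivity(p, fhi)), p$eps_inf,
                 tolerance = 1e-3)
  }
  # alpha -> 0 continuity
  a0 <- dispersion_params(4, 40, 1, 8e-12, 0)
  a1 <- dispersion_params(4, 40, 1, 8e-12, 1e-9)
  f <- c(1e9, 15e9, 110e9)
  expect_lt(max(Mod(complex_permittivity(a1, f) -
                      complex_permittivity(a0, f)) /
                  Mod(complex_permittivity(a0, f))), 1e-6)
})

test_that("loss tangent is zero for lossless media and ratio-exact otherwise", {
  expect_equal(loss_tangent(ptfe_params(), 30e9), 0)
  # conduction-only medium built so eps = 2 - 0.004i at 10 GHz
  f <- 10e9
  sig <- 0.004 * phys_constants()$eps0 * 2 * pi * f
  m <- dispersion_params(2, 2, sig, 0)
  expect_equal(loss_tangent(m, f), 0.002, tolerance = 1e-12)
  expect_gt(loss_tangent(gel_params(), 30e9), 0)
  expect_true(is.finite(loss_tangent(gel_params(), 30e9)))
})

test_that("Debye surrogate fit reproduces Debye sources and tracks the gel", {
  # identity case: fitting a Debye source returns its own dispersion
  src <- dispersion_params(4, 35, 1.5, 9e-12)
  fitted <- fit_debye_to_dispersion(src, c(15e9, 40e9))
  f <- exp(seq(log(15e9), log(40e9), length.out = 20))
  rel <- Mod(complex_permittivity(fitted, f) - complex_permittivity(src, f)) /
    Mod(complex_permittivity(src, f))
  expect_lt(max(rel), 1e-6)

  # broadened gel model: Debye surrogate within 2% over the WR28 band
  deb <- fit_debye_to_dispersion(gel_params(), c(21e9, 42e9))
  expect_equal(deb$alpha, 0)
  expect_lt(attr(deb, "residual_max_rel"), 0.02)

  expect_error(fit_debye_to_dispersion(gel_params(), c(30e9, 30e9)),
               "degenerate band")
  expect_error(fit_debye_to_dispersion(gel_params(), c(21e9, 42e9),
                                       n_points = 3), "n_points")
})
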