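test_that("probe registry geometry and band/cutoff preconditions are enforced", {
  wg <- wr_probe("WR28")
  expect_equal(wg$a, 7.112e-3)
  expect_equal(wg$b, 3.556e-3)
  expect_lt(wg$f_cutoff, wg$f_lo)
  expect_setequal(wr_probe(), c("WR42", "WR28", "WR15", "WR10"))
  expect_error(wr_probe("WR90"), "unknown probe")
  expect_error(rect_waveguide("x", 1e-3, 2e-3, 10e9, 20e9), "a > b")
  expect_error(rect_waveguide("x", 7.112e-3, 3.556e-3, 20e9, 42e9), "cutoff")

  reg <- skin_registry()
  expect_error(te10_reflection(wg, reg$stacks$gel_bare, 10e9), "cutoff")
  expect_error(te10_reflection(wg, reg$stacks$gel_bare, 50e9), "usable band")
})

test_that("short-circuit limit and passivity hold at the reference plane", {
  wg <- wr_probe("WR28")
  reg <- skin_registry()
  expect_equal(te10_reflection(wg, reg$stacks$gel_bare, 30e9, short = TRUE),
               -1 + 0i)
  # metal-like half-space termination approaches the ideal short
  pec <- layer_stack(layer(dispersion_params(1, 1, 1e9, 0), Inf))
  s <- te10_reflection(wg, pec, 30e9)
  expect_lt(Mod(s + 1), 1e-3)
  # passive stacks stay inside the unit circle across the band
  for (f in c(22e9, 30e9, 42e9)) {
    for (nm in c("gel_ptfe100", "skin_thin_mean", "skin_thick_mean")) {
      expect_lt(Mod(te10_reflection(wg, reg$stacks[[nm]], f)), 1)
    }
  }
})

test_that("full and parity-reduced mode bases agree on the TE10 coefficient", {
  wg <- wr_probe("WR28")
  reg <- skin_registry()
  st_red <- mm_settings(n_modes = 24, reduced = TRUE, n_ang = 10,
                        n_rad_prop = 24, n_rad_evan = 12)
  # full basis sized so it contains every coupled mode of the reduced basis
  red_tab <- skinwave:::.mode_table(wg$a, wg$b, 24, TRUE)
  nfull <- 40L
  repeat {
    full_tab <- skinwave:::.mode_table(wg$a, wg$b, nfull, FALSE)
    have <- paste(full_tab$fam, full_tab$m, full_tab$n)
    if (all(paste(red_tab$fam, red_tab$m, red_tab$n) %in% have)) break
    nfull <- nfull + 20L
  }
  st_full <- mm_settings(n_modes = nfull, reduced = FALSE, n_ang = 10,
                         n_rad_prop = 24, n_rad_evan = 12)
  s_red <- te10_reflection(wg, reg$stacks$gel_ptfe100, 30e9, st_red)
  s_full <- te10_reflection(wg, reg$stacks$gel_ptfe100, 30e9, st_full)
  expect_lt(Mod(s_red - s_full), 1e-8)
})

test_that("solution is self-convergent under doubled truncation", {
  wg <- wr_probe("WR28")
  reg <- skin_registry()
  st <- mm_settings()
  s1 <- te10_reflection(wg, reg$stacks$gel_ptfe100, 30e9, st)
  s2 <- te10_reflection(wg, reg$stacks$gel_ptfe100, 30e9,
                        mm_settings_doubled(st))
  expect_lt(abs(20 * log10(Mod(s1)) - 20 * log10(Mod(s2))), st$tol)
})

test_that("fringing fields contribute measurably for low-permittivity covers", {
  # the aperture-coupled solution must differ from the naive single-mode
  # transverse-resonance approximation somewhere in band
  wg <- wr_probe("WR28")
  reg <- skin_registry()
  fs <- c(22e9, 30e9, 42e9)
  mm_db <- 20 * log10(Mod(te10_reflection(wg, reg$stacks$gel_ptfe100, fs)))
  nv_db <- 20 * log10(Mod(te10_transverse_resonance(
    wg, reg$stacks$gel_ptfe100, fs)))
  expect_gt(max(abs(mm_db - nv_db)), 0.05)
})

test_that("spectra are vectorized, smooth and carry provenance metadata", {
  wg <- wr_probe("WR42")
  reg <- skin_registry()
  f1 <- 20e9
  sp1 <- s11_spectrum(wg, reg$stacks$skin_thin_mean, f1)
  expect_equal(sp1$s11, te10_reflection(wg, reg$stacks$skin_thin_mean, f1))

  fg <- seq(16e9, 28e9, by = 1e9)
  sp <- s11_spectrum(wg, reg$stacks$skin_thin_mean, fg)
  expect_equal(nrow(sp), length(fg))
  # smooth curve: < 0.2 dB change per 0.1 GHz, checked at 1 GHz spacing
  expect_lt(max(abs(diff(sp$s11_db))), 0.2 / 0.1 * 1)
  meta <- attr(sp, "meta")
  expect_equal(meta$probe, "WR42")
  expect_equal(meta$stack, "skin_thin_mean")
  expect_equal(meta$settings$n_modes, mm_settings()$n_modes)
})
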