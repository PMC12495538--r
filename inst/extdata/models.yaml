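# Dispersive material models and named stacks.
#
# Materials: gel and PTFE are the validation targets (tissue-simulating gel
# coated with 50/100 um PTFE); the skin entries are the fitted two-layer skin
# models: an effective inner layer ("Layer D") for the population mean and
# the 68%/95% coverage factors, a thin stratum corneum (literature
# parameters, fixed 20 um), and three thick-stratum-corneum models whose
# thicknesses correspond to the mean and the 68th/95th percentiles of the
# thick-SC population.
#
# Units: d_um in micrometers (.inf marks a terminal half-space), tau_ps in
# picoseconds, sigma_S_per_m in S/m.
materials:
  - {name: gel,          d_um: .inf, eps_inf: 4.62, eps_s: 42.5, sigma_S_per_m: 1.02, tau_ps: 11.8, alpha: 0.075}
  - {name: ptfe_50,      d_um: 50,   eps_inf: 2.1,  eps_s: 2.1,  sigma_S_per_m: 0,    tau_ps: 0,    alpha: 0}
  - {name: ptfe_100,     d_um: 100,  eps_inf: 2.1,  eps_s: 2.1,  sigma_S_per_m: 0,    tau_ps: 0,    alpha: 0}
  - {name: foam,         d_um: 4800, eps_inf: 1.09, eps_s: 1.09, sigma_S_per_m: 0,    tau_ps: 0,    alpha: 0}
  - {name: layer_d_mean, d_um: .inf, eps_inf: 7.88, eps_s: 47.0, sigma_S_per_m: 5.19, tau_ps: 8.35, alpha: 0}
  - {name: layer_d_p68,  d_um: .inf, eps_inf: 5.06, eps_s: 37.0, sigma_S_per_m: 7.62, tau_ps: 8.19, alpha: 0}
  - {name: layer_d_p95,  d_um: .inf, eps_inf: 2.98, eps_s: 32.8, sigma_S_per_m: 6.94, tau_ps: 8.76, alpha: 0}
  - {name: sc_thin,      d_um: 20,   eps_inf: 2.96, eps_s: 4.46, sigma_S_per_m: 0,    tau_ps: 6.9,  alpha: 0}
  - {name: sc_thick1,    d_um: 227,  eps_inf: 4.01, eps_s: 9.11, sigma_S_per_m: 0,    tau_ps: 1.63, alpha: 0}
  - {name: sc_thick2,    d_um: 262,  eps_inf: 3.27, eps_s: 8.22, sigma_S_per_m: 0,    tau_ps: 2.04, alpha: 0}
  - {name: sc_thick3,    d_um: 295,  eps_inf: 2.49, eps_s: 7.29, sigma_S_per_m: 0,    tau_ps: 2.22, alpha: 0}
stacks:
  - {name: gel_bare,       layers: [gel]}
  - {name: gel_ptfe50,     layers: [ptfe_50, gel]}
  - {name: gel_ptfe100,    layers: [ptfe_100, gel]}
  - {name: skin_thin_mean, layers: [sc_thin, layer_d_mean]}
  - {name: skin_thin_p68,  layers: [sc_thin, layer_d_p68]}
  - {name: skin_thin_p95,  layers: [sc_thin, layer_d_p95]}
  - {name: skin_thick_mean, layers: [sc_thick1, layer_d_mean]}
  - {name: skin_thick_p68, layers: [sc_thick2, layer_d_mean]}
  - {name: skin_thick_p95, layers: [sc_thick3, layer_d_mean]}
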