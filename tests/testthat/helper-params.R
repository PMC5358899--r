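# report every failure rather than aborting the run at the default cap
testthat::set_max_fails(Inf)

# shared fixtures: the standard parameter sets (r0 = 0.8, D_T/D_R = 37,
# n = 3) at the three featured positive-feedback ratios
p_fast <- dimensionless_params(tau_e = 0.1, tau_d0 = 1)
p_mid <- dimensionless_params(tau_e = 1, tau_d0 = 1)
p_slow <- dimensionless_params(tau_e = 3, tau_d0 = 1)

# physical cells matched to tau_E = 1, tau_D0 = 1 in an exponential ramp of
# unit decay length (t_M = v0 = 1)
mp_unit <- model_params(t_m = 1, N = 1, H = 1, v0 = 1,
                        d_r = 1 / (2 * 8.2), d_t = 37 / (2 * 8.2))
g_ramp <- gradient_profile("exponential", C0 = 1, L0 = 1,
                           saturating = FALSE, geometry = "planar")
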