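# Ground truth mirroring the published system: endothermic cis binding,
# mildly exothermic trans binding, a ~10 kJ/mol ligand-induced drop in the
# isomerisation barrier; laws anchored at the 21 degC measurements.
canonical_truth <- function(seed = 1L, cis_purity = 1) {
  study_truth(
    delta_h_cis = 130e3,
    delta_s_cis = entropy_from_anchor(130e3, kd_ref = 7.0e-6, t_ref = 294.15),
    delta_h_trans = -50e3,
    delta_s_trans = entropy_from_anchor(-50e3, kd_ref = 3.8e-6, t_ref = 294.15),
    delta_h_act_p = 89e3,
    prefactor_p = prefactor_from_anchor(89e3, tau_ref = 2.68 * 3600, t_ref = 294.15),
    delta_h_act_pl = 79e3,
    prefactor_pl = prefactor_from_anchor(79e3, tau_ref = 2.25 * 3600, t_ref = 294.15),
    cis_purity = cis_purity,
    seed = seed
  )
}

# minimal regression-fit stubs for cycle-level tests (enthalpies and SEs
# chosen by the test, everything else irrelevant to assembly)
make_vh <- function(delta_h, se = 0, state = "cis") {
  structure(list(state = state, delta_h = delta_h, delta_h_se = se,
                 delta_s = 0, delta_s_se = 0, slope = -delta_h / phys_const$R,
                 intercept = 0, cov_slope_intercept = 0, n_points = 4L,
                 standard_state = 1, weighted = FALSE),
            class = "vant_hoff_fit")
}

make_arr <- function(delta_h_act, se = 0, condition = "P") {
  structure(list(condition = condition, delta_h_act = delta_h_act,
                 delta_h_act_se = se, prefactor_a = 1e11,
                 prefactor_log_se = 0, slope = -delta_h_act / phys_const$R,
                 intercept = log(1e11), cov_slope_intercept = 0,
                 n_points = 4L, weighted = FALSE),
            class = "arrhenius_fit")
}

# independent solver of the binding equilibrium: bisection on
# f(PL) = (p0 - PL)(l0 - PL)/PL - kd, which is strictly decreasing on
# (0, min(p0, l0))
bisect_complex <- function(kd, p0, l0, tol = 1e-16) {
  if (p0 == 0 || l0 == 0) return(0)
  f <- function(pl) (p0 - pl) * (l0 - pl) / pl - kd
  lo <- min(p0, l0) * 1e-300
  hi <- min(p0, l0)
  for (i in 1:2000) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) < tol * hi) break
  }
  (lo + hi) / 2
}
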