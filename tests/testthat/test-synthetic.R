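test_that("noiseless titration signals follow the exact depletion isotherm", {
  truth <- titration_truth(kd_true = 25e-6, l0 = 15e-6,
                           p0_grid = c(0, 10e-6, 50e-6),
                           signal_free = 1, signal_bound = 0, noise_sd = 0)
  tr <- generate_titration(truth)
  frac <- 1 - tr$points$signal  # endpoints 1 -> 0
  expect_equal(frac[1], 0)                      # no protein, no complex
  expect_equal(frac[3], 0.6195, tolerance = 1e-4)
  # stoichiometric limit
  tight <- generate_titration(titration_truth(kd_true = 1e-15, l0 = 15e-6,
                                              p0_grid = 50e-6, noise_sd = 0,
                                              signal_free = 1, signal_bound = 0))
  expect_equal(1 - tight$points$signal, 1, tolerance = 1e-6)
})

test_that("noiseless relaxation traces follow the exponential law", {
  tau <- 2.68 * 3600
  truth <- relaxation_truth(tau_true = tau, a_start = 0.2, a_end = 1.0,
                            time_grid = c(0, tau, 2 * tau), noise_sd = 0)
  tr <- generate_relaxation(truth)
  a <- tr$samples$absorbance_370
  expect_equal(a[1], 0.2)                               # t = 0
  expect_equal(a[2], 1.0 + (0.2 - 1.0) / exp(1))        # one e-folding
  expect_equal(a[3], 1.0 - 0.8 * exp(-2), tolerance = 1e-10)
  expect_equal(a[3], 0.8917, tolerance = 1e-4)
})

test_that("generation is deterministic in the seed", {
  t1 <- generate_titration(titration_truth(kd_true = 7e-6, noise_sd = 0.02, seed = 7L))
  t2 <- generate_titration(titration_truth(kd_true = 7e-6, noise_sd = 0.02, seed = 7L))
  t3 <- generate_titration(titration_truth(kd_true = 7e-6, noise_sd = 0.02, seed = 8L))
  expect_identical(t1, t2)
  expect_false(identical(t1$points$signal, t3$points$signal))
  s1 <- generate_study(canonical_truth(seed = 3L))
  s2 <- generate_study(canonical_truth(seed = 3L))
  expect_identical(s1, s2)
  # the generator must not disturb the caller's RNG stream
  set.seed(99); before <- stats::rnorm(1)
  set.seed(99); invisible(generate_study(canonical_truth(seed = 3L)))
  expect_identical(stats::rnorm(1), before)
})

test_that("noiseless bound fraction is non-decreasing in protein concentration", {
  for (kd in c(1e-7, 7e-6, 1e-4)) {
    tr <- generate_titration(titration_truth(kd_true = kd, noise_sd = 0))
    frac <- 1 - tr$points$signal
    expect_true(all(diff(frac) >= 0))
  }
})

test_that("study laws reproduce the anchored two-point extrapolations", {
  truth <- canonical_truth()
  expect_equal(true_kd(truth, 294.15, "trans"), 3.8e-6, tolerance = 1e-12)
  expect_equal(true_kd(truth, 283.15, "trans") * 1e6, 1.72, tolerance = 2e-3)
  expect_equal(true_kd(truth, 313.15, "cis") * 1e6, 0.278, tolerance = 2e-3)
  expect_equal(true_tau(truth, 294.15, "P") / 3600, 2.68, tolerance = 1e-12)
  # doubling the rate between two temperatures halves tau
  k1 <- 1 / true_tau(truth, 294.15, "P")
  t2 <- 1 / (1 / 294.15 - phys_const$R * log(2) / 89e3)
  expect_equal(1 / true_tau(truth, t2, "P"), 2 * k1, tolerance = 1e-9)
})

test_that("a photostationary state below 100% cis mixes in trans signal", {
  pure <- generate_study(canonical_truth(seed = 2L),
                         titration_template = list(noise_sd = 0))
  mixed <- generate_study(canonical_truth(seed = 2L, cis_purity = 0.85),
                          titration_template = list(noise_sd = 0))
  nm <- "cis_294.15K"
  expected <- 0.85 * pure$titrations[[nm]]$points$signal +
    0.15 * pure$titrations[["trans_294.15K"]]$points$signal
  expect_equal(mixed$titrations[[nm]]$points$signal, expected, tolerance = 1e-12)
  # trans series unaffected
  expect_identical(mixed$titrations[["trans_294.15K"]],
                   pure$titrations[["trans_294.15K"]])
})

test_that("invalid ground truths are rejected", {
  expect_error(titration_truth(kd_true = -1e-6), "kd_true")
  expect_error(titration_truth(kd_true = Inf), "kd_true")
  expect_error(titration_truth(kd_true = 1e-6, noise_sd = -0.1), "noise_sd")
  expect_error(titration_truth(kd_true = 1e-6, signal_free = 1, signal_bound = 1),
               "differ")
  expect_error(relaxation_truth(tau_true = 0), "tau_true")
  expect_error(relaxation_truth(tau_true = 10, time_grid = c(3, 2, 1)),
               "increasing")
  expect_error(relaxation_truth(tau_true = 10, time_grid = numeric(0)),
               "non-empty")
  tr <- canonical_truth()
  expect_error(study_truth(130e3, 500, -50e3, -70, 89e3, 1e11, 79e3, 1e10,
                           temperatures = 294.15), "2 distinct")
  expect_error(study_truth(130e3, 500, -50e3, -70, 89e3, -1, 79e3, 1e10),
               "prefactor_p")
  expect_error(study_truth(130e3, 500, -50e3, -70, 89e3, 1e11, 79e3, 1e10,
                           cis_purity = 1.2), "cis_purity")
})

test_that("the full pipeline recovers every ground-truth parameter without noise", {
  truth <- canonical_truth(seed = 5L)
  study <- generate_study(truth, titration_template = list(noise_sd = 0),
                          relaxation_template = list(noise_sd = 0))
  res <- analyze_study(study)
  tol <- 1e-4
  expect_equal(res$vant_hoff$cis$delta_h, truth$delta_h_cis, tolerance = tol)
  expect_equal(res$vant_hoff$cis$delta_s, truth$delta_s_cis, tolerance = tol)
  expect_equal(res$vant_hoff$trans$delta_h, truth$delta_h_trans, tolerance = tol)
  expect_equal(res$vant_hoff$trans$delta_s, truth$delta_s_trans, tolerance = tol)
  expect_equal(res$arrhenius$P$delta_h_act, truth$delta_h_act_p, tolerance = tol)
  expect_equal(res$arrhenius$PL$delta_h_act, truth$delta_h_act_pl, tolerance = tol)
  expect_equal(res$arrhenius$P$prefactor_a, truth$prefactor_p, tolerance = tol)
  expect_equal(res$arrhenius$PL$prefactor_a, truth$prefactor_pl, tolerance = tol)
  for (f in res$affinities) {
    expect_equal(f$kd, true_kd(truth, f$temperature, f$state), tolerance = tol)
  }
  for (f in res$rates) {
    expect_equal(f$tau, true_tau(truth, f$temperature, f$condition), tolerance = tol)
  }
  expect_equal(res$cycle$ddh / 1000, 180, tolerance = tol)
  expect_equal(res$cycle$ddh_act / 1000, -10, tolerance = tol)
  expect_equal(res$cycle$phi, 120 / 130, tolerance = tol)
  expect_equal(res$cycle$force * 1e9, 0.9963, tolerance = 1e-3)
})
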