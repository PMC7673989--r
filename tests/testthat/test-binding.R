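test_that("bound_complex solves the depletion quadratic exactly", {
  # 25 uM Kd, 50 uM protein, 15 uM ligand: root of the quadratic
  pl <- bound_complex(25e-6, 50e-6, 15e-6)
  expect_equal(pl, 9.293e-6, tolerance = 1e-4)
  # back-substitution reproduces Kd
  expect_equal((50e-6 - pl) * (15e-6 - pl) / pl, 25e-6, tolerance = 1e-10)
  # no protein, no complex
  expect_identical(bound_complex(25e-6, 0, 15e-6), 0)
  # stoichiometric limit: PL -> min(p0, l0)
  expect_equal(bound_complex(1e-15, 50e-6, 15e-6) / 15e-6, 1, tolerance = 1e-6)
})

test_that("bound_complex is symmetric in the two species", {
  set.seed(42)
  for (i in 1:20) {
    kd <- 10^stats::runif(1, -9, -4)
    a <- 10^stats::runif(1, -8, -4)
    b <- 10^stats::runif(1, -8, -4)
    expect_identical(bound_complex(kd, a, b), bound_complex(kd, b, a))
  }
})

test_that("bound_complex matches a bisection oracle over a wide grid", {
  kds <- 10^seq(-12, -2, length.out = 6)
  concs <- 10^seq(-9, -3, length.out = 5)
  for (kd in kds) for (p0 in concs) for (l0 in concs) {
    pl <- bound_complex(kd, p0, l0)
    expect_lte(pl, min(p0, l0) * (1 + 1e-12))
    expect_gte(pl, 0)
    expect_equal(pl, bisect_complex(kd, p0, l0), tolerance = 1e-12)
  }
})

test_that("the stable form survives extreme affinity without cancellation", {
  # kd / min(p0, l0) down to 1e-12: complex must stay at the stoichiometric
  # limit, not blow up from subtracting nearly equal numbers
  for (kd in 10^seq(-12, -18, by = -2)) {
    pl <- bound_complex(kd, 50e-6, 15e-6)
    expect_equal(pl, 15e-6, tolerance = 1e-6)
    expect_true(is.finite(pl))
  }
  expect_error(bound_complex(25e-6, -1e-6, 15e-6), "p0")
  expect_error(bound_complex(NaN, 1e-6, 15e-6), "kd")
})

test_that("normalization maps references to 0 and 1 and keeps overshoot", {
  raw <- titration_series(p0 = c(0, 1e-6, 2e-6, 5e-6),
                          signal = c(100, 60, 25, 15),
                          l0 = 15e-6, temperature = 294.15, state = "cis")
  norm <- normalize_titration(raw, zero_reference = 100, full_reference = 20)
  expect_equal(norm$points$fraction_bound, c(0, 0.5, 0.9375, 1.0625))
  expect_true(norm$normalized)
  # quenching direction (full < zero) handled; overshoot retained, not clipped
  expect_gt(max(norm$points$fraction_bound), 1)
  expect_error(normalize_titration(raw, 100, 100), "degenerate")
})

test_that("plateau_signal averages the highest-concentration points", {
  raw <- titration_series(p0 = c(0, 10e-6, 40e-6, 50e-6),
                          signal = c(100, 60, 22, 20),
                          l0 = 15e-6, temperature = 294.15, state = "trans")
  expect_equal(plateau_signal(raw), 21)
})

test_that("fit_kd recovers a noiseless synthetic Kd to high precision", {
  for (kd_true in c(7.0e-6, 1.4e-6, 22e-6)) {
    tr <- generate_titration(titration_truth(kd_true = kd_true, noise_sd = 0))
    norm <- normalize_titration(tr, zero_reference = 1, full_reference = 0)
    fit <- fit_kd(norm, plateau = "fit")
    expect_true(fit$converged)
    expect_equal(fit$kd, kd_true, tolerance = 1e-6)
  }
})

test_that("fit_kd recovers Kd under realistic noise (Monte Carlo)", {
  kd_true <- 1.8e-6
  errs <- vapply(1:200, function(seed) {
    tr <- generate_titration(titration_truth(kd_true = kd_true,
                                             noise_sd = 0.02, seed = seed))
    norm <- normalize_titration(tr, zero_reference = 1, full_reference = 0)
    abs(fit_kd(norm)$kd - kd_true) / kd_true
  }, 0)
  expect_lt(stats::median(errs), 0.10)
})

test_that("fit_kd rejects unidentifiable series", {
  flat <- titration_series(p0 = rep(10e-6, 5),
                           fraction_bound = c(0.5, 0.52, 0.49, 0.51, 0.5),
                           l0 = 15e-6, temperature = 294.15, state = "cis")
  expect_error(fit_kd(flat), "distinct")
  zeros <- titration_series(p0 = c(0, 1e-6, 2e-6, 5e-6),
                            fraction_bound = rep(0, 4),
                            l0 = 15e-6, temperature = 294.15, state = "cis")
  expect_error(fit_kd(zeros), "unidentifiable")
  short <- titration_series(p0 = c(0, 1e-6, 2e-6), fraction_bound = c(0, .2, .4),
                            l0 = 15e-6, temperature = 294.15, state = "cis")
  expect_error(fit_kd(short), "4")
  raw <- generate_titration(titration_truth(kd_true = 7e-6, noise_sd = 0))
  expect_error(fit_kd(raw), "normalized")
})

test_that("raising all bound fractions tightens the fitted Kd", {
  tr <- generate_titration(titration_truth(kd_true = 7e-6, noise_sd = 0))
  norm <- normalize_titration(tr, zero_reference = 1, full_reference = 0)
  base <- fit_kd(norm, plateau = "fixed")$kd
  boosted <- norm
  boosted$points$fraction_bound <- pmin(norm$points$fraction_bound * 1.15, 0.999)
  expect_lt(fit_kd(boosted, plateau = "fixed")$kd, base)
})
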