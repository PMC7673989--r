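test_that("two-point van't Hoff agrees with the closed form", {
  # Ka doubles from 283.15 to 313.15 K
  t1 <- 283.15; t2 <- 313.15
  d <- data.frame(temperature = c(t1, t2), kd = c(2e-6, 1e-6))
  fit <- vant_hoff(d, state = "trans")
  dh_closed <- phys_const$R * log(2) / (1 / t1 - 1 / t2)
  expect_equal(fit$delta_h, dh_closed, tolerance = 1e-12)
  expect_equal(fit$delta_h / 1000, 17.0, tolerance = 2e-3)
  expect_true(is.na(fit$delta_h_se))  # undefined for 2 points
  # temperature-independent Kd means zero enthalpy
  flat <- vant_hoff(data.frame(temperature = c(283.15, 294.15, 313.15),
                               kd = rep(5e-6, 3)), state = "cis")
  expect_equal(flat$delta_h, 0, tolerance = 1e-9)
})

test_that("van't Hoff on the published Kd series reproduces the enthalpies", {
  tb <- table1()
  temp_k <- celsius_to_kelvin(tb$temperature_c)
  fit_cis <- vant_hoff(data.frame(temperature = temp_k, kd = tb$kd_cis_um * 1e-6),
                       state = "cis")
  fit_trans <- vant_hoff(data.frame(temperature = temp_k, kd = tb$kd_trans_um * 1e-6),
                         state = "trans")
  # independent check: textbook OLS slope formula on (1/T, ln Ka)
  ols_dh <- function(kd) {
    x <- 1 / temp_k; y <- -log(kd)
    -phys_const$R * sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  expect_equal(fit_cis$delta_h, ols_dh(tb$kd_cis_um * 1e-6), tolerance = 1e-12)
  expect_equal(fit_trans$delta_h, ols_dh(tb$kd_trans_um * 1e-6), tolerance = 1e-12)
  expect_equal(fit_cis$delta_h / 1000, 126.89, tolerance = 1e-4)
  expect_equal(fit_trans$delta_h / 1000, -51.23, tolerance = 1e-4)
  # endothermic cis binding comes with strong entropic stabilisation
  expect_gt(fit_cis$delta_s, 0)
  expect_lt(fit_trans$delta_s, 0)
})

test_that("two-point Arrhenius agrees with the closed form", {
  t1 <- 283.15; t2 <- 293.15
  d <- data.frame(temperature = c(t1, t2), k = c(1e-5, 2e-5))
  fit <- arrhenius(d, condition = "P")
  dh_closed <- phys_const$R * log(2) / (1 / t1 - 1 / t2)
  expect_equal(fit$delta_h_act, dh_closed, tolerance = 1e-12)
  expect_equal(fit$delta_h_act / 1000, 47.8, tolerance = 1e-3)
  # tau input is equivalent to k = 1/tau
  fit_tau <- arrhenius(data.frame(temperature = c(t1, t2), tau = 1 / c(1e-5, 2e-5)),
                       condition = "P")
  expect_equal(fit_tau$delta_h_act, fit$delta_h_act, tolerance = 1e-12)
})

test_that("Arrhenius on the published tau series reproduces the barriers", {
  tb <- table1()
  temp_k <- celsius_to_kelvin(tb$temperature_c)
  fit_p <- arrhenius(data.frame(temperature = temp_k, tau = tb$tau_p_h * 3600),
                     condition = "P")
  fit_pl <- arrhenius(data.frame(temperature = temp_k, tau = tb$tau_pl_h * 3600),
                      condition = "PL")
  expect_equal(fit_p$delta_h_act / 1000, 88.76, tolerance = 1e-3)
  expect_equal(fit_pl$delta_h_act / 1000, 79.44, tolerance = 1e-3)
  # prefactors are order-of-magnitude quantities: ~5e11 and ~1.5e10 1/s
  expect_equal(log10(fit_p$prefactor_a), log10(5.47e11), tolerance = 1e-2)
  expect_equal(log10(fit_pl$prefactor_a), log10(1.54e10), tolerance = 1e-2)
  expect_gt(fit_p$prefactor_a, 0)
})

test_that("standard state fixes the entropy convention", {
  tb <- table1()
  temp_k <- celsius_to_kelvin(tb$temperature_c)
  in_molar <- vant_hoff(data.frame(temperature = temp_k, kd = tb$kd_cis_um * 1e-6),
                        state = "cis")
  # feeding bare uM numbers (i.e. a 1 uM standard state) shifts the entropy
  # by exactly R ln 1e6 and leaves the enthalpy untouched
  in_micromolar <- vant_hoff(data.frame(temperature = temp_k, kd = tb$kd_cis_um),
                             state = "cis")
  expect_equal(in_micromolar$delta_h, in_molar$delta_h, tolerance = 1e-12)
  expect_equal(in_molar$delta_s - in_micromolar$delta_s,
               phys_const$R * log(1e6), tolerance = 1e-9)
})

test_that("weighted regression honours the per-point uncertainties", {
  tb <- table1()
  temp_k <- celsius_to_kelvin(tb$temperature_c)
  d <- data.frame(temperature = temp_k, kd = tb$kd_cis_um * 1e-6,
                  kd_se = tb$kd_cis_se_um * 1e-6)
  wfit <- vant_hoff(d, state = "cis", weighted = TRUE)
  ufit <- vant_hoff(d, state = "cis", weighted = FALSE)
  expect_false(isTRUE(all.equal(wfit$delta_h, ufit$delta_h)))
  expect_true(is.finite(wfit$delta_h_se))
  expect_error(vant_hoff(d[, 1:2], state = "cis", weighted = TRUE), "standard errors")
})

test_that("regression inputs are validated", {
  expect_error(vant_hoff(data.frame(temperature = 294.15, kd = 1e-6)),
               "2 distinct")
  expect_error(vant_hoff(data.frame(temperature = c(280, 290), k = c(1, 2))),
               "kd")
  expect_error(arrhenius(data.frame(temperature = c(280, 290), kd = c(1, 2))),
               "'k' or 'tau'")
  # duplicate temperatures with conflicting values are allowed, both used
  fit <- vant_hoff(data.frame(temperature = c(283.15, 283.15, 313.15),
                              kd = c(1e-6, 1.2e-6, 5e-6)), state = "cis")
  expect_equal(fit$n_points, 3L)
})

test_that("the Eyring frequency factor is linear in temperature", {
  expect_equal(signif(eyring_prefactor(303.15), 2), 6.3e12)
  expect_equal(eyring_prefactor(606.30), 2 * eyring_prefactor(303.15))
  expect_equal(eyring_prefactor(1e-25), 0, tolerance = 1e-6)
  expect_error(eyring_prefactor(0), "temperature")
})

test_that("prediction inverts the fitted regressions exactly", {
  # noiseless 2-point fit interpolates through both points
  d <- data.frame(temperature = c(283.15, 313.15), kd = c(2e-6, 9e-6))
  fit <- vant_hoff(d, state = "trans")
  expect_equal(predict_kd(fit, 283.15), 2e-6, tolerance = 1e-12)
  expect_equal(predict_kd(fit, 313.15), 9e-6, tolerance = 1e-12)
  # anchored extrapolations
  vh <- vant_hoff_from_anchor(-50e3, kd_ref = 3.8e-6, t_ref = 294.15)
  expect_equal(predict_kd(vh, 283.15) * 1e6, 1.72, tolerance = 2e-3)
  vh_cis <- vant_hoff_from_anchor(130e3, kd_ref = 7.0e-6, t_ref = 294.15)
  expect_equal(predict_kd(vh_cis, 313.15) * 1e6, 0.278, tolerance = 2e-3)
  arr <- arrhenius_from_anchor(89e3, tau_ref = 2.68 * 3600, t_ref = 294.15)
  expect_equal(predict_tau(arr, 294.15) / 3600, 2.68, tolerance = 1e-12)
  # rate doubling implies tau halving
  ratio <- predict_tau(arr, 294.15) / predict_tau(arr, 304.15)
  k_ratio <- (1 / predict_tau(arr, 304.15)) / (1 / predict_tau(arr, 294.15))
  expect_equal(ratio, k_ratio)
})

test_that("regression plot data lie on the fitted line", {
  d <- data.frame(temperature = c(283.15, 294.15, 313.15), kd = c(2e-6, 4e-6, 9e-6))
  fit <- vant_hoff(d, state = "trans")
  line <- regression_line(fit, d$temperature)
  expect_equal(line$ln_value, fit$intercept + fit$slope / d$temperature)
  expect_equal(exp(-line$ln_value), predict_kd(fit, d$temperature))
})
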