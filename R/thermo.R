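#' Van't Hoff regression of binding affinities
#'
#' Ordinary least squares of `ln(Ka)` against `1/T`, with
#' `Ka = (1 mol/L)/Kd` (1 M standard state), over a temperature series of
#' dissociation constants for one photoswitch state. The binding enthalpy
#' and entropy follow from slope and intercept:
#' `dH = -R * slope`, `dS = R * intercept` (sign convention: the binding
#' direction P + L -> PL; a positive slope of ln Ka vs 1/T means exothermic
#' binding). The enthalpy is treated as temperature-independent over the
#' fitted range (straight-line van't Hoff).
#'
#' @param x either a data.frame with columns `temperature` (K) and `kd`
#'   (mol/L), optionally `kd_se`, or a list of `affinity_fit` objects from
#'   [fit_kd()].
#' @param state photoswitch state label stored on the result; taken from the
#'   fits if `x` is a list of estimates and `state` is missing.
#' @param weighted if `TRUE`, weight points by `1/se(ln Ka)^2` with
#'   `se(ln Ka) = kd_se/kd` (requires `kd_se`). Default unweighted.
#' @return Object of class `vant_hoff_fit`: `delta_h`, `delta_h_se` (J/mol),
#'   `delta_s`, `delta_s_se` (J/(mol K)), `slope`, `intercept`,
#'   `cov_slope_intercept`, `n_points`, `state`, `standard_state` (1 mol/L).
#'   For `n_points = 2` the standard errors are `NA`.
#' @export
#' @examples
#' tb <- table1()
#' vant_hoff(data.frame(temperature = celsius_to_kelvin(tb$temperature_c),
#'                      kd = tb$kd_cis_um * 1e-6), state = "cis")
vant_hoff <- function(x, state = NULL, weighted = FALSE) {
  d <- as_temperature_table(x, value = "kd", label_field = "state")
  if (is.null(state)) state <- d$label
  ln_ka <- -log(d$tab$kd)           # Ka = 1/Kd, both relative to 1 M
  se_ln <- if (!is.null(d$tab[["kd_se"]])) d$tab[["kd_se"]] / d$tab$kd else NULL
  reg <- thermo_regression(ln_ka, d$tab$temperature, se_ln, weighted)
  structure(list(
    state = state,
    delta_h = -phys_const$R * reg$slope,
    delta_h_se = phys_const$R * reg$slope_se,
    delta_s = phys_const$R * reg$intercept,
    delta_s_se = phys_const$R * reg$intercept_se,
    slope = reg$slope, intercept = reg$intercept,
    cov_slope_intercept = reg$cov,
    n_points = reg$n, standard_state = 1,
    weighted = weighted
  ), class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf(
    "van't Hoff (%s, n = %d): dH = %.1f +/- %.1f kJ/mol, dS = %.1f +/- %.1f J/(mol K)\n",
    x$state, x$n_points, x$delta_h / 1000, x$delta_h_se / 1000,
    x$delta_s, x$delta_s_se))
  invisible(x)
}

#' Arrhenius regression of isomerisation rates
#'
#' Ordinary least squares of `ln(k)` against `1/T` over a temperature series
#' of thermal cis-to-trans isomerisation rates for one ligation condition
#' (free protein P or ligand-bound PL). Activation enthalpy and
#' pre-exponential factor follow from `dH_act = -R * slope`,
#' `A = exp(intercept)` (1/s). The uncertainty of `A` is reported on the log
#' scale (`prefactor_log_se`, the SE of `ln A`), since the sampling
#' distribution of an extrapolated intercept is log-scale.
#'
#' @param x either a data.frame with columns `temperature` (K) and one of
#'   `k` (1/s) or `tau` (s), optionally `tau_se`, or a list of `rate_fit`
#'   objects from [fit_monoexponential()].
#' @param condition ligation condition label (`"P"` or `"PL"`); taken from
#'   the fits when `x` is a list of estimates.
#' @param weighted if `TRUE`, weight by `1/se(ln k)^2` with
#'   `se(ln k) = tau_se/tau`.
#' @return Object of class `arrhenius_fit`: `delta_h_act`,
#'   `delta_h_act_se` (J/mol), `prefactor_a` (1/s), `prefactor_log_se`,
#'   `slope`, `intercept`, `cov_slope_intercept`, `n_points`, `condition`.
#' @export
#' @examples
#' tb <- table1()
#' arrhenius(data.frame(temperature = celsius_to_kelvin(tb$temperature_c),
#'                      tau = tb$tau_p_h * 3600), condition = "P")
arrhenius <- function(x, condition = NULL, weighted = FALSE) {
  d <- as_temperature_table(x, value = "k", label_field = "condition")
  if (is.null(condition)) condition <- d$label
  ln_k <- log(d$tab$k)
  se_ln <- if (!is.null(d$tab[["tau_se"]]) && !is.null(d$tab[["tau"]])) {
    d$tab[["tau_se"]] / d$tab[["tau"]]
  } else NULL
  reg <- thermo_regression(ln_k, d$tab$temperature, se_ln, weighted)
  structure(list(
    condition = condition,
    delta_h_act = -phys_const$R * reg$slope,
    delta_h_act_se = phys_const$R * reg$slope_se,
    prefactor_a = exp(reg$intercept),
    prefactor_log_se = reg$intercept_se,
    slope = reg$slope, intercept = reg$intercept,
    cov_slope_intercept = reg$cov,
    n_points = reg$n,
    weighted = weighted
  ), class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "Arrhenius (%s, n = %d): dH_act = %.1f +/- %.1f kJ/mol, A = %.2g 1/s (se ln A = %.2g)\n",
    x$condition, x$n_points, x$delta_h_act / 1000, x$delta_h_act_se / 1000,
    x$prefactor_a, x$prefactor_log_se))
  invisible(x)
}

# internal: coerce estimate lists / data.frames to a temperature table
as_temperature_table <- function(x, value, label_field) {
  label <- NULL
  want_class <- if (value == "kd") "affinity_fit" else "rate_fit"
  if (is.list(x) && !is.data.frame(x) && length(x) > 0 &&
      all(vapply(x, inherits, TRUE, what = want_class))) {
    labels <- unique(vapply(x, `[[`, "", label_field))
    if (length(labels) != 1L) {
      stop(sprintf("all estimates must share one %s; got: %s",
                   label_field, paste(labels, collapse = ", ")), call. = FALSE)
    }
    label <- labels
    tab <- data.frame(
      temperature = vapply(x, `[[`, 0, "temperature"),
      stringsAsFactors = FALSE
    )
    if (value == "kd") {
      tab$kd <- vapply(x, `[[`, 0, "kd")
      tab$kd_se <- vapply(x, `[[`, 0, "kd_se")
    } else {
      tab$tau <- vapply(x, `[[`, 0, "tau")
      tab$tau_se <- vapply(x, `[[`, 0, "tau_se")
      tab$k <- 1 / tab$tau
    }
  } else if (is.data.frame(x)) {
    tab <- x
    # [[ ]] indexing: $ would partial-match e.g. a 'kd' column for 'k'
    if (is.null(tab[["temperature"]])) {
      stop("data.frame input needs a 'temperature' column (K)", call. = FALSE)
    }
    if (value == "k" && is.null(tab[["k"]])) {
      if (is.null(tab[["tau"]])) stop("need a 'k' or 'tau' column", call. = FALSE)
      tab$k <- 1 / tab[["tau"]]
    }
    if (value == "kd" && is.null(tab[["kd"]])) {
      stop("need a 'kd' column (mol/L)", call. = FALSE)
    }
  } else {
    stop("input must be a data.frame or a list of estimates", call. = FALSE)
  }
  if (any(tab$temperature <= 0)) stop("temperatures must be in Kelvin (> 0)",
                                      call. = FALSE)
  if (length(unique(tab$temperature)) < 2L) {
    stop("need at least 2 distinct temperatures", call. = FALSE)
  }
  list(tab = tab, label = label)
}

# internal: OLS/WLS of y on 1/T with slope/intercept covariance
thermo_regression <- function(y, temperature, se_ln = NULL, weighted = FALSE) {
  inv_t <- 1 / temperature
  w <- NULL
  if (weighted) {
    if (is.null(se_ln) || any(!is.finite(se_ln)) || any(se_ln <= 0)) {
      stop("weighted fit needs positive standard errors for every point",
           call. = FALSE)
    }
    w <- 1 / se_ln^2
  }
  fit <- stats::lm(y ~ inv_t, weights = w)
  cf <- stats::coef(fit)
  n <- length(y)
  if (n > 2L) {
    # suppressWarnings: summary.lm warns on essentially perfect (noiseless) fits
    vc <- suppressWarnings(stats::vcov(fit))
    slope_se <- sqrt(vc[2, 2]); intercept_se <- sqrt(vc[1, 1]); cov <- vc[1, 2]
  } else {
    slope_se <- NA_real_; intercept_se <- NA_real_; cov <- NA_real_
  }
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       slope_se = slope_se, intercept_se = intercept_se, cov = cov, n = n)
}

#' Eyring frequency factor kB*T/h
#'
#' The transition-state-theory attempt frequency at temperature `T`,
#' for comparison with fitted Arrhenius pre-exponential factors.
#'
#' @param temperature temperature in Kelvin (> 0). Vectorized.
#' @return `kB * T / h` in 1/s (about 6.3e12 1/s near 303 K).
#' @export
#' @examples
#' eyring_prefactor(303.15)
eyring_prefactor <- function(temperature) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("'temperature' must be finite and > 0", call. = FALSE)
  }
  phys_const$kB * temperature / phys_const$h
}

#' Predict Kd or tau from a fitted temperature regression
#'
#' Exact inverses of the [vant_hoff()] and [arrhenius()] regression models,
#' for interpolation, recovery tests and plotting.
#'
#' @param fit a `vant_hoff_fit` or `arrhenius_fit`.
#' @param temperature temperature(s) in Kelvin (> 0).
#' @return `predict_kd`: dissociation constant (mol/L);
#'   `predict_tau`: time constant (s).
#' @export
predict_kd <- function(fit, temperature) {
  stopifnot(inherits(fit, "vant_hoff_fit"))
  if (any(temperature <= 0)) stop("'temperature' must be > 0", call. = FALSE)
  # ln Ka = intercept + slope / T;  Kd = 1/Ka
  exp(-(fit$intercept + fit$slope / temperature))
}

#' @rdname predict_kd
#' @export
predict_tau <- function(fit, temperature) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  if (any(temperature <= 0)) stop("'temperature' must be > 0", call. = FALSE)
  # ln k = intercept + slope / T;  tau = 1/k
  exp(-(fit$intercept + fit$slope / temperature))
}

#' Build temperature laws from an enthalpy and one anchor point
#'
#' Construct a `vant_hoff_fit` from a binding enthalpy plus one known
#' `Kd(T_ref)`, or an `arrhenius_fit` from an activation enthalpy plus one
#' known `tau(T_ref)`. These are the generative counterparts of the
#' regressions: the synthetic-study generator and anchored extrapolation
#' examples use them.
#'
#' @param delta_h binding enthalpy (J/mol).
#' @param kd_ref dissociation constant (mol/L) at `t_ref`.
#' @param t_ref anchor temperature (K).
#' @param state,condition labels stored on the result.
#' @return A `vant_hoff_fit` / `arrhenius_fit` with `NA` standard errors.
#' @export
#' @examples
#' vh <- vant_hoff_from_anchor(-50e3, kd_ref = 3.8e-6, t_ref = 294.15)
#' predict_kd(vh, 283.15) * 1e6  # 1.72 uM
vant_hoff_from_anchor <- function(delta_h, kd_ref, t_ref, state = "trans") {
  check_scalar(delta_h, "delta_h")
  check_scalar(kd_ref, "kd_ref", positive = TRUE)
  check_scalar(t_ref, "t_ref", positive = TRUE)
  slope <- -delta_h / phys_const$R
  intercept <- -log(kd_ref) - slope / t_ref
  structure(list(
    state = state, delta_h = delta_h, delta_h_se = NA_real_,
    delta_s = phys_const$R * intercept, delta_s_se = NA_real_,
    slope = slope, intercept = intercept, cov_slope_intercept = NA_real_,
    n_points = 1L, standard_state = 1, weighted = FALSE
  ), class = "vant_hoff_fit")
}

#' @rdname vant_hoff_from_anchor
#' @param delta_h_act activation enthalpy (J/mol).
#' @param tau_ref time constant (s) at `t_ref`.
#' @export
arrhenius_from_anchor <- function(delta_h_act, tau_ref, t_ref, condition = "P") {
  check_scalar(delta_h_act, "delta_h_act")
  check_scalar(tau_ref, "tau_ref", positive = TRUE)
  check_scalar(t_ref, "t_ref", positive = TRUE)
  slope <- -delta_h_act / phys_const$R
  intercept <- -log(tau_ref) - slope / t_ref
  structure(list(
    condition = condition, delta_h_act = delta_h_act,
    delta_h_act_se = NA_real_,
    prefactor_a = exp(intercept), prefactor_log_se = NA_real_,
    slope = slope, intercept = intercept, cov_slope_intercept = NA_real_,
    n_points = 1L, weighted = FALSE
  ), class = "arrhenius_fit")
}

#' Regression plot data for a van't Hoff or Arrhenius fit
#'
#' The (x, y) coordinates the fits are drawn in: `x = 1/T`, `y = ln Ka` or
#' `ln k`, for export as CSV.
#'
#' @param fit a `vant_hoff_fit` or `arrhenius_fit`.
#' @param temperature temperatures (K) at which to evaluate the fitted line.
#' @return data.frame with columns `inv_temperature` and `ln_value`.
#' @export
regression_line <- function(fit, temperature) {
  stopifnot(inherits(fit, "vant_hoff_fit") || inherits(fit, "arrhenius_fit"))
  data.frame(inv_temperature = 1 / temperature,
             ln_value = fit$intercept + fit$slope / temperature)
}
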