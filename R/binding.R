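#' Construct a titration series
#'
#' One fluorescence-quenching titration: fixed initial ligand concentration
#' `l0`, a grid of initial protein concentrations `p0`, and either a raw
#' signal or an already-normalized fraction of bound ligand per point, at one
#' temperature and photoswitch state.
#'
#' @param p0 numeric vector of initial protein concentrations (mol/L).
#' @param signal raw fluorescence signals (arbitrary units), or `NULL` if
#'   `fraction_bound` is given.
#' @param fraction_bound normalized fraction of bound ligand, or `NULL` if
#'   `signal` is given. Values slightly outside \[0, 1\] are allowed (noise).
#' @param l0 initial ligand concentration (mol/L), shared by all points.
#' @param temperature temperature in Kelvin.
#' @param state one of `"cis"`, `"trans"`, `"wild_type"`.
#' @return An object of class `titration_series`: a list with elements
#'   `state`, `temperature`, `l0`, `normalized`, and `points` (a data.frame
#'   with columns `p0` and `signal` or `fraction_bound`).
#' @export
#' @examples
#' titration_series(p0 = c(0, 5, 15, 50) * 1e-6, signal = c(100, 80, 60, 35),
#'                  l0 = 15e-6, temperature = 294.15, state = "cis")
titration_series <- function(p0, signal = NULL, fraction_bound = NULL,
                             l0, temperature, state = c("cis", "trans", "wild_type")) {
  state <- match.arg(state)
  check_scalar(l0, "l0", positive = TRUE)
  check_scalar(temperature, "temperature", positive = TRUE)
  if (!is.numeric(p0) || length(p0) < 1L || any(!is.finite(p0))) {
    stop("'p0' must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (any(p0 < 0)) stop("'p0' must be >= 0", call. = FALSE)
  normalized <- !is.null(fraction_bound)
  if (normalized == !is.null(signal)) {
    stop("give exactly one of 'signal' or 'fraction_bound'", call. = FALSE)
  }
  y <- if (normalized) fraction_bound else signal
  if (!is.numeric(y) || length(y) != length(p0) || any(!is.finite(y))) {
    stop("signal/fraction_bound must be finite and match length(p0)", call. = FALSE)
  }
  points <- data.frame(p0 = as.numeric(p0))
  points[[if (normalized) "fraction_bound" else "signal"]] <- as.numeric(y)
  structure(
    list(state = state, temperature = temperature, l0 = l0,
         normalized = normalized, points = points),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series (%s, %.2f K): l0 = %.3g M, %d points, %s\n",
              x$state, x$temperature, x$l0, nrow(x$points),
              if (x$normalized) "normalized" else "raw signal"))
  invisible(x)
}

#' Equilibrium complex concentration under ligand depletion
#'
#' Solves the two-state binding equilibrium
#' `Kd = (p0 - PL)(l0 - PL) / PL` exactly for the complex concentration
#' `PL`, without the dilute-ligand approximation. The physically admissible
#' (smaller) root of `PL^2 - (p0 + l0 + kd) PL + p0 l0 = 0` is computed in
#' the cancellation-free form
#' `PL = 2 p0 l0 / (b + sqrt(b^2 - 4 p0 l0))`, `b = p0 + l0 + kd`,
#' which stays accurate down to the stoichiometric limit `kd -> 0`.
#'
#' @param kd dissociation constant (mol/L), > 0.
#' @param p0 initial protein concentration (mol/L), >= 0. Vectorized.
#' @param l0 initial ligand concentration (mol/L), >= 0.
#' @return Complex concentration `PL` (mol/L), with `0 <= PL <= min(p0, l0)`.
#' @export
#' @examples
#' bound_complex(kd = 25e-6, p0 = 50e-6, l0 = 15e-6)  # 9.293e-06
bound_complex <- function(kd, p0, l0) {
  check_scalar(kd, "kd", positive = TRUE)
  if (!is.numeric(p0) || any(!is.finite(p0)) || any(p0 < 0)) {
    stop("'p0' must be finite and >= 0", call. = FALSE)
  }
  check_scalar(l0, "l0", nonnegative = TRUE)
  b <- p0 + l0 + kd
  # b^2 - 4 p0 l0 expanded to a sum of nonnegative terms: evaluating it
  # directly loses the discriminant to rounding when p0 ~ l0 >> kd
  disc <- (p0 - l0)^2 + kd * (2 * (p0 + l0) + kd)
  2 * p0 * l0 / (b + sqrt(disc))
}

#' Normalize a raw titration to fraction of bound ligand
#'
#' Applies the 0%/100% convention: the signal of ligand alone (no protein)
#' defines 0% bound and the saturating-plateau signal defines 100% bound;
#' `fraction_bound = (signal - zero_reference) / (full_reference -
#' zero_reference)`. Works for quenching, where the bound signal is the
#' smaller one. The cis and trans series of one temperature should share the
#' same pair of references (plateau taken from the stronger binder).
#'
#' @param raw a raw (non-normalized) [titration_series].
#' @param zero_reference signal corresponding to 0% bound (AU).
#' @param full_reference signal corresponding to 100% bound (AU); must
#'   differ from `zero_reference`.
#' @return A normalized `titration_series` with a `fraction_bound` column.
#'   Values outside \[0, 1\] are retained, not clipped.
#' @seealso [plateau_signal()] for the default 100% reference.
#' @export
normalize_titration <- function(raw, zero_reference, full_reference) {
  stopifnot(inherits(raw, "titration_series"))
  if (raw$normalized) stop("series is already normalized", call. = FALSE)
  check_scalar(zero_reference, "zero_reference")
  check_scalar(full_reference, "full_reference")
  if (full_reference == zero_reference) {
    stop("zero_reference and full_reference must differ (degenerate scale)",
         call. = FALSE)
  }
  frac <- (raw$points$signal - zero_reference) / (full_reference - zero_reference)
  titration_series(p0 = raw$points$p0, fraction_bound = frac,
                   l0 = raw$l0, temperature = raw$temperature, state = raw$state)
}

#' Plateau (100% bound) reference signal of a titration
#'
#' Mean signal of the `n_top` largest-protein-concentration points; used as
#' the saturating-plateau reference for normalization, taken from the
#' stronger binder of a cis/trans pair.
#'
#' @param raw a raw [titration_series].
#' @param n_top number of top-`p0` points to average (default 2).
#' @return Mean signal (AU).
#' @export
plateau_signal <- function(raw, n_top = 2L) {
  stopifnot(inherits(raw, "titration_series"))
  if (raw$normalized) stop("plateau reference needs raw signals", call. = FALSE)
  ord <- order(raw$points$p0, decreasing = TRUE)
  mean(raw$points$signal[ord[seq_len(min(n_top, nrow(raw$points)))]])
}

#' Fit the dissociation constant to a normalized titration
#'
#' Least-squares fit of the exact ligand-depletion isotherm
#' `fraction_bound(p0) = PL(kd, p0, l0) / l0` (see [bound_complex()]) to a
#' normalized titration series, by unweighted nonlinear least squares
#' (Levenberg-Marquardt). With `plateau = "fit"` an additional
#' multiplicative scale on the saturation level is estimated as a nuisance
#' parameter, for curves that do not reach their plateau.
#'
#' @param series a normalized [titration_series] with at least 4 points and
#'   at least 2 distinct `p0` values.
#' @param plateau `"fixed"` (default; saturation level is exactly 1 after
#'   normalization) or `"fit"` (a free scale multiplies the isotherm).
#' @return An object of class `affinity_fit`: list with `kd`, `kd_se`
#'   (mol/L, from the fit curvature), `state`, `temperature`, `l0`,
#'   `n_points`, `residual_sd`, `converged`, and (if fitted) `plateau_scale`.
#' @export
#' @examples
#' tr <- generate_titration(titration_truth(kd_true = 7e-6, l0 = 15e-6,
#'   p0_grid = seq(0, 50e-6, length.out = 12), noise_sd = 0))
#' tr <- normalize_titration(tr, zero_reference = 1, full_reference = 0)
#' fit_kd(tr)$kd  # 7e-06
fit_kd <- function(series, plateau = c("fixed", "fit")) {
  plateau <- match.arg(plateau)
  stopifnot(inherits(series, "titration_series"))
  if (!series$normalized) {
    stop("fit_kd() needs a normalized series; see normalize_titration()",
         call. = FALSE)
  }
  pts <- series$points
  if (nrow(pts) < 4L) stop("need at least 4 titration points", call. = FALSE)
  if (length(unique(pts$p0)) < 2L) {
    stop("unidentifiable: need at least 2 distinct protein concentrations",
         call. = FALSE)
  }
  if (all(abs(pts$fraction_bound) < sqrt(.Machine$double.eps))) {
    stop("unidentifiable: all fractions bound are zero", call. = FALSE)
  }
  l0 <- series$l0
  # start where the curve crosses half saturation; fallback median p0
  half <- which.min(abs(pts$fraction_bound - 0.5))
  kd0 <- pts$p0[half]
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(pts$p0[pts$p0 > 0])
  y <- pts$fraction_bound
  p0 <- pts$p0
  # fit log(kd): keeps kd positive without a box constraint (at a kd -> 0
  # corner the finite-difference gradient underflows and the fit stalls)
  fit <- if (plateau == "fixed") {
    lm_least_squares(
      function(par) y - bound_complex(exp(par[["log_kd"]]), p0, l0) / l0,
      start = c(log_kd = log(kd0))
    )
  } else {
    lm_least_squares(
      function(par) y - par[["scale"]] *
        bound_complex(exp(par[["log_kd"]]), p0, l0) / l0,
      start = c(log_kd = log(kd0), scale = 1),
      lower = c(log_kd = -Inf, scale = 1e-6)
    )
  }
  kd_hat <- exp(unname(fit$par[["log_kd"]]))
  out <- list(
    kd = kd_hat,
    kd_se = kd_hat * unname(fit$se[["log_kd"]]),  # delta method from log scale
    state = series$state,
    temperature = series$temperature,
    l0 = l0,
    n_points = nrow(pts),
    residual_sd = fit$sigma,
    converged = fit$converged
  )
  if (plateau == "fit") out$plateau_scale <- unname(fit$par[["scale"]])
  if (!out$converged) {
    warning("Kd fit did not converge; estimates are unreliable", call. = FALSE)
  }
  structure(out, class = "affinity_fit")
}

#' @export
print.affinity_fit <- function(x, ...) {
  cat(sprintf("Kd (%s, %.2f K): %.4g +/- %.2g M  [n = %d, residual sd %.3g%s]\n",
              x$state, x$temperature, x$kd, x$kd_se, x$n_points, x$residual_sd,
              if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}
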