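#' Construct a thermal relaxation trace
#'
#' Absorbance at 370 nm (the trans-state absorption maximum) versus time,
#' recorded while the photoswitch relaxes thermally from cis back to trans,
#' for either the free protein (`"P"`) or the ligand-bound complex (`"PL"`)
#' at one temperature.
#'
#' @param time sampling times (seconds), strictly increasing, first >= 0.
#' @param absorbance_370 absorbance at 370 nm (AU), same length as `time`.
#' @param temperature temperature in Kelvin.
#' @param condition `"P"` (free protein) or `"PL"` (ligand bound).
#' @return An object of class `relaxation_trace`.
#' @export
relaxation_trace <- function(time, absorbance_370, temperature,
                             condition = c("P", "PL")) {
  condition <- match.arg(condition)
  check_scalar(temperature, "temperature", positive = TRUE)
  if (!is.numeric(time) || length(time) < 1L || any(!is.finite(time))) {
    stop("'time' must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (time[1] < 0 || any(diff(time) <= 0)) {
    stop("'time' must start >= 0 and be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(absorbance_370) || length(absorbance_370) != length(time) ||
      any(!is.finite(absorbance_370))) {
    stop("'absorbance_370' must be finite and match length(time)", call. = FALSE)
  }
  structure(
    list(condition = condition, temperature = temperature,
         samples = data.frame(time = as.numeric(time),
                              absorbance_370 = as.numeric(absorbance_370))),
    class = "relaxation_trace"
  )
}

#' @export
print.relaxation_trace <- function(x, ...) {
  cat(sprintf("Relaxation trace (%s, %.2f K): %d samples over %.3g s\n",
              x$condition, x$temperature, nrow(x$samples),
              diff(range(x$samples$time))))
  invisible(x)
}

#' Fit a mono-exponential relaxation
#'
#' Nonlinear least-squares fit of
#' `A(t) = offset + amplitude * exp(-t / tau)` to an absorbance-vs-time
#' trace, extracting the thermal cis-to-trans isomerisation time constant
#' `tau` (and rate `k = 1/tau`). Starting values come from the trace
#' endpoints and a log-linearization of the first half of the trace; the
#' offset floats by default but can be pinned (e.g. to the dark-adapted
#' absorbance) via `fix_offset`.
#'
#' @param trace a [relaxation_trace] with at least 5 samples. A span shorter
#'   than one time constant draws a warning (tau poorly constrained), not an
#'   error.
#' @param fix_offset optional numeric: hold the asymptotic absorbance fixed
#'   at this value instead of fitting it.
#' @return An object of class `rate_fit`: list with `tau`, `tau_se` (s),
#'   `k = 1/tau` (1/s), `amplitude`, `offset` (AU), `condition`,
#'   `temperature`, `n_points`, `residual_sd`, `converged`.
#' @export
#' @examples
#' tr <- generate_relaxation(relaxation_truth(tau_true = 2.68 * 3600,
#'   a_start = 0.2, a_end = 1.0,
#'   time_grid = seq(0, 8 * 3600, length.out = 40), noise_sd = 0))
#' fit_monoexponential(tr)$tau / 3600  # 2.68 h
fit_monoexponential <- function(trace, fix_offset = NULL) {
  stopifnot(inherits(trace, "relaxation_trace"))
  s <- trace$samples
  if (nrow(s) < 5L) stop("need at least 5 samples", call. = FALSE)
  a <- s$absorbance_370
  t <- s$time
  if (diff(range(a)) == 0) {
    stop("unidentifiable: constant absorbance (zero amplitude)", call. = FALSE)
  }
  offset0 <- if (is.null(fix_offset)) a[length(a)] else fix_offset
  amplitude0 <- a[1] - offset0
  if (amplitude0 == 0) amplitude0 <- a[1] - mean(a)
  # tau0 from ln|A - offset0| over the first half, where the residual signal
  # is well above the asymptote
  half <- seq_len(max(3L, floor(length(t) / 2)))
  resid0 <- abs(a[half] - offset0)
  ok <- resid0 > 1e-12 * max(abs(a), 1)
  tau0 <- if (sum(ok) >= 2) {
    sl <- unname(stats::coef(stats::lm(log(resid0[ok]) ~ t[half][ok]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 2
  } else {
    diff(range(t)) / 2
  }
  fit <- if (is.null(fix_offset)) {
    lm_least_squares(
      function(par) a - (par[["offset"]] + par[["amplitude"]] * exp(-t / par[["tau"]])),
      start = c(offset = offset0, amplitude = amplitude0, tau = tau0),
      lower = c(offset = -Inf, amplitude = -Inf, tau = 1e-12)
    )
  } else {
    lm_least_squares(
      function(par) a - (fix_offset + par[["amplitude"]] * exp(-t / par[["tau"]])),
      start = c(amplitude = amplitude0, tau = tau0),
      lower = c(amplitude = -Inf, tau = 1e-12)
    )
  }
  tau <- unname(fit$par[["tau"]])
  amplitude <- unname(fit$par[["amplitude"]])
  amp_se <- unname(fit$se[["amplitude"]])
  if (is.finite(amp_se) && amp_se > 0 && abs(amplitude) < amp_se) {
    stop("unidentifiable: amplitude indistinguishable from zero", call. = FALSE)
  }
  if (diff(range(t)) < tau) {
    warning("trace spans less than one fitted time constant; tau is poorly constrained",
            call. = FALSE)
  }
  out <- structure(list(
    tau = tau,
    tau_se = unname(fit$se[["tau"]]),
    k = 1 / tau,
    amplitude = amplitude,
    offset = if (is.null(fix_offset)) unname(fit$par[["offset"]]) else fix_offset,
    condition = trace$condition,
    temperature = trace$temperature,
    n_points = nrow(s),
    residual_sd = fit$sigma,
    converged = fit$converged
  ), class = "rate_fit")
  if (!out$converged) {
    warning("relaxation fit did not converge; estimates are unreliable",
            call. = FALSE)
  }
  out
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf(
    "tau (%s, %.2f K): %.4g +/- %.2g s  (k = %.4g 1/s; n = %d%s)\n",
    x$condition, x$temperature, x$tau, x$tau_se, x$k, x$n_points,
    if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}

#' Photostationary cis fraction from 370 nm absorbances
#'
#' Estimates the cis fraction reached under illumination from the ratio of
#' absorbances at 370 nm before (`a_dark`, pure trans) and during/after
#' illumination (`a_illuminated`), under the approximation that the pure cis
#' state does not absorb at 370 nm: `fraction = 1 - a_illuminated / a_dark`.
#'
#' @param a_illuminated absorbance at 370 nm in the photostationary state (AU).
#' @param a_dark absorbance at 370 nm of the dark-adapted (trans) sample
#'   (AU), > 0.
#' @return cis fraction in \[0, 1\]. Ratios outside \[0, 1\] are clipped
#'   with a warning.
#' @export
#' @examples
#' estimate_cis_fraction(0.15, 1.0)  # 0.85
estimate_cis_fraction <- function(a_illuminated, a_dark) {
  check_scalar(a_dark, "a_dark", positive = TRUE)
  check_scalar(a_illuminated, "a_illuminated")
  ratio <- a_illuminated / a_dark
  if (ratio < 0 || ratio > 1) {
    warning("absorbance ratio outside [0, 1]; clipping", call. = FALSE)
    ratio <- min(max(ratio, 0), 1)
  }
  1 - ratio
}
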