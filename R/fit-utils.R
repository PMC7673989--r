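# Shared Levenberg-Marquardt driver for the nonlinear fits.
#
# Uses the residual-function interface of minpack.lm::nls.lm rather than the
# formula interface: the formula path rebuilds an nls model object whose QR
# of the numeric gradient can be singular in nearly degenerate regimes
# (e.g. stoichiometric binding, kd << l0), even when the parameter of
# interest is perfectly well determined. Standard errors come from the
# Jacobian at the optimum, sigma^2 (J'J)^-1; if that curvature matrix is
# numerically singular the SEs are NA, not an error.
lm_least_squares <- function(residual_fn, start, lower = NULL, upper = NULL) {
  nm <- names(start)
  fn <- function(p) {
    names(p) <- nm    # nls.lm may strip names mid-iteration
    residual_fn(p)
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = fn,
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15, gtol = 0)
  )
  par <- fit$par
  names(par) <- nm
  r <- residual_fn(par)
  n <- length(r)
  p <- length(par)
  dof <- max(n - p, 1L)
  sigma <- sqrt(sum(r^2) / dof)
  se <- rep(NA_real_, p)
  names(se) <- names(par)
  cov <- tryCatch({
    # fit$hessian = J'J at the solution
    sigma^2 * solve(fit$hessian)
  }, error = function(e) NULL)
  if (!is.null(cov)) {
    d <- diag(cov)
    se[d >= 0] <- sqrt(d[d >= 0])
  }
  converged <- fit$info %in% 1:4
  list(par = par, se = se, sigma = sigma, converged = converged,
       message = fit$message, niter = fit$niter)
}
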