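# Synthetic data with the statistical structure the analysis assumes:
# exact ligand-depletion binding, van't Hoff Kd(T), mono-exponential
# relaxation with Arrhenius tau(T), homoscedastic Gaussian noise.

# run expr with a temporary RNG state; leaves the caller's RNG untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Ground truth for one synthetic titration
#'
#' @param kd_true true dissociation constant (mol/L), > 0.
#' @param l0 initial ligand concentration (mol/L), > 0; default 15 uM.
#' @param p0_grid initial protein concentrations (mol/L); default 12 points
#'   spanning 0-50 uM.
#' @param signal_free fluorescence signal of fully free ligand (AU).
#' @param signal_bound signal of fully bound ligand (AU); quenching means
#'   `signal_bound < signal_free`. Must differ from `signal_free`.
#' @param noise_sd Gaussian noise SD (signal units), >= 0.
#' @param seed integer random seed.
#' @return Object of class `titration_truth`.
#' @export
titration_truth <- function(kd_true, l0 = 15e-6,
                            p0_grid = seq(0, 50e-6, length.out = 12),
                            signal_free = 1, signal_bound = 0,
                            noise_sd = 0.02, seed = 1L) {
  check_scalar(kd_true, "kd_true", positive = TRUE)
  check_scalar(l0, "l0", positive = TRUE)
  check_scalar(signal_free, "signal_free")
  check_scalar(signal_bound, "signal_bound")
  check_scalar(noise_sd, "noise_sd", nonnegative = TRUE)
  if (!is.numeric(p0_grid) || any(!is.finite(p0_grid)) || any(p0_grid < 0)) {
    stop("'p0_grid' must be finite and >= 0", call. = FALSE)
  }
  if (signal_free == signal_bound) {
    stop("signal_free and signal_bound must differ", call. = FALSE)
  }
  structure(list(kd_true = kd_true, l0 = l0, p0_grid = as.numeric(p0_grid),
                 signal_free = signal_free, signal_bound = signal_bound,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "titration_truth")
}

#' Ground truth for one synthetic relaxation trace
#'
#' @param tau_true true time constant (s), > 0.
#' @param a_start absorbance at t = 0 (AU).
#' @param a_end asymptotic absorbance (AU).
#' @param time_grid sampling times (s), strictly increasing, first >= 0;
#'   default 50 points over 3 time constants.
#' @param noise_sd Gaussian noise SD (AU), >= 0.
#' @param seed integer random seed.
#' @return Object of class `relaxation_truth`.
#' @export
relaxation_truth <- function(tau_true, a_start = 0.2, a_end = 1.0,
                             time_grid = seq(0, 3 * tau_true, length.out = 50),
                             noise_sd = 0.008, seed = 1L) {
  check_scalar(tau_true, "tau_true", positive = TRUE)
  check_scalar(a_start, "a_start")
  check_scalar(a_end, "a_end")
  check_scalar(noise_sd, "noise_sd", nonnegative = TRUE)
  if (!is.numeric(time_grid) || length(time_grid) < 1L ||
      any(!is.finite(time_grid))) {
    stop("'time_grid' must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (time_grid[1] < 0 || any(diff(time_grid) <= 0)) {
    stop("'time_grid' must start >= 0 and be strictly increasing", call. = FALSE)
  }
  structure(list(tau_true = tau_true, a_start = a_start, a_end = a_end,
                 time_grid = as.numeric(time_grid), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "relaxation_truth")
}

#' Generate a synthetic titration series
#'
#' Noiseless signal per point:
#' `signal_free + (signal_bound - signal_free) * PL / l0`, with the complex
#' concentration `PL` from the exact ligand-depletion solution
#' ([bound_complex()]); homoscedastic Gaussian noise on top. The protein's
#' own fluorescence contribution is modelled as zero (negligible in the
#' measurement this emulates).
#'
#' @param truth a [titration_truth].
#' @param state,temperature labels stored on the series (the single-series
#'   generator does not itself use them; [generate_study()] sets them).
#' @return A raw (non-normalized) [titration_series]. Identical truth and
#'   seed give identical output.
#' @export
generate_titration <- function(truth, state = "cis", temperature = 294.15) {
  stopifnot(inherits(truth, "titration_truth"))
  frac <- bound_complex(truth$kd_true, truth$p0_grid, truth$l0) / truth$l0
  sig <- truth$signal_free + (truth$signal_bound - truth$signal_free) * frac
  if (truth$noise_sd > 0) {
    sig <- sig + with_seed(truth$seed,
                           stats::rnorm(length(sig), 0, truth$noise_sd))
  }
  titration_series(p0 = truth$p0_grid, signal = sig, l0 = truth$l0,
                   temperature = temperature, state = state)
}

#' Generate a synthetic relaxation trace
#'
#' `A(t) = a_end + (a_start - a_end) * exp(-t / tau_true)` plus Gaussian
#' noise.
#'
#' @param truth a [relaxation_truth].
#' @param condition,temperature labels stored on the trace.
#' @return A [relaxation_trace]. Identical truth and seed give identical
#'   output.
#' @export
generate_relaxation <- function(truth, condition = "P", temperature = 294.15) {
  stopifnot(inherits(truth, "relaxation_truth"))
  a <- truth$a_end +
    (truth$a_start - truth$a_end) * exp(-truth$time_grid / truth$tau_true)
  if (truth$noise_sd > 0) {
    a <- a + with_seed(truth$seed, stats::rnorm(length(a), 0, truth$noise_sd))
  }
  relaxation_trace(time = truth$time_grid, absorbance_370 = a,
                   temperature = temperature, condition = condition)
}

#' Ground truth for a whole multi-temperature study
#'
#' Defines the generative laws of a complete experiment: per photoswitch
#' state a binding enthalpy and entropy (1 M standard state) fixing
#' `Kd(T)` through the van't Hoff relation
#' `ln Ka(T) = -dH/(R T) + dS/R`; per ligation condition an activation
#' enthalpy and pre-exponential factor fixing `tau(T) = 1/k(T)` through the
#' Arrhenius relation `k(T) = A exp(-dH_act/(R T))`. An optional
#' photostationary cis purity below 1 mixes residual trans signal into the
#' generated cis titrations.
#'
#' @param delta_h_cis,delta_h_trans binding enthalpies (J/mol).
#' @param delta_s_cis,delta_s_trans binding entropies (J/(mol K), 1 M
#'   standard state). See [entropy_from_anchor()] to set them from one known
#'   Kd.
#' @param delta_h_act_p,delta_h_act_pl activation enthalpies (J/mol).
#' @param prefactor_p,prefactor_pl Arrhenius pre-exponential factors (1/s),
#'   > 0. See [prefactor_from_anchor()].
#' @param temperatures at least 2 distinct temperatures (K); default the
#'   10/21/30/40 degC series.
#' @param cis_purity photostationary cis fraction in \[0, 1\]; default 1
#'   (no residual-trans correction).
#' @param delta_x anchor-distance change (m); default 3 Angstrom.
#' @param seed integer master seed; per-dataset seeds are derived from it.
#' @return Object of class `study_truth`.
#' @export
study_truth <- function(delta_h_cis, delta_s_cis, delta_h_trans, delta_s_trans,
                        delta_h_act_p, prefactor_p,
                        delta_h_act_pl, prefactor_pl,
                        temperatures = celsius_to_kelvin(c(10, 21, 30, 40)),
                        cis_purity = 1, delta_x = 3e-10, seed = 1L) {
  for (nm in c("delta_h_cis", "delta_s_cis", "delta_h_trans", "delta_s_trans",
               "delta_h_act_p", "delta_h_act_pl")) {
    check_scalar(get(nm), nm)
  }
  check_scalar(prefactor_p, "prefactor_p", positive = TRUE)
  check_scalar(prefactor_pl, "prefactor_pl", positive = TRUE)
  check_scalar(cis_purity, "cis_purity", nonnegative = TRUE)
  check_scalar(delta_x, "delta_x", positive = TRUE)
  if (cis_purity > 1) stop("'cis_purity' must be in [0, 1]", call. = FALSE)
  if (length(unique(temperatures)) < 2L || any(temperatures <= 0)) {
    stop("need at least 2 distinct positive temperatures (K)", call. = FALSE)
  }
  structure(list(
    delta_h_cis = delta_h_cis, delta_s_cis = delta_s_cis,
    delta_h_trans = delta_h_trans, delta_s_trans = delta_s_trans,
    delta_h_act_p = delta_h_act_p, prefactor_p = prefactor_p,
    delta_h_act_pl = delta_h_act_pl, prefactor_pl = prefactor_pl,
    temperatures = sort(unique(as.numeric(temperatures))),
    cis_purity = cis_purity, delta_x = delta_x, seed = as.integer(seed)
  ), class = "study_truth")
}

#' Entropy / prefactor implied by an enthalpy and one anchor measurement
#'
#' `entropy_from_anchor()` returns the binding entropy (J/(mol K), 1 M
#' standard state) that makes the van't Hoff law with enthalpy `delta_h`
#' pass through `Kd(t_ref) = kd_ref`; `prefactor_from_anchor()` returns the
#' Arrhenius prefactor (1/s) that makes the rate law with activation
#' enthalpy `delta_h_act` pass through `tau(t_ref) = tau_ref`.
#'
#' @param delta_h binding enthalpy (J/mol).
#' @param kd_ref dissociation constant (mol/L) at `t_ref`.
#' @param t_ref anchor temperature (K).
#' @return Entropy in J/(mol K), or prefactor in 1/s.
#' @export
#' @examples
#' entropy_from_anchor(130e3, kd_ref = 7.0e-6, t_ref = 294.15)
entropy_from_anchor <- function(delta_h, kd_ref, t_ref) {
  check_scalar(delta_h, "delta_h")
  check_scalar(kd_ref, "kd_ref", positive = TRUE)
  check_scalar(t_ref, "t_ref", positive = TRUE)
  phys_const$R * (-log(kd_ref)) + delta_h / t_ref
}

#' @rdname entropy_from_anchor
#' @param delta_h_act activation enthalpy (J/mol).
#' @param tau_ref time constant (s) at `t_ref`.
#' @export
prefactor_from_anchor <- function(delta_h_act, tau_ref, t_ref) {
  check_scalar(delta_h_act, "delta_h_act")
  check_scalar(tau_ref, "tau_ref", positive = TRUE)
  check_scalar(t_ref, "t_ref", positive = TRUE)
  (1 / tau_ref) * exp(delta_h_act / (phys_const$R * t_ref))
}

#' True Kd and tau at a temperature under a study ground truth
#'
#' @param truth a [study_truth].
#' @param temperature temperature (K).
#' @param state `"cis"` or `"trans"` (for `true_kd`).
#' @param condition `"P"` or `"PL"` (for `true_tau`).
#' @return Kd in mol/L, or tau in seconds.
#' @export
true_kd <- function(truth, temperature, state = c("cis", "trans")) {
  stopifnot(inherits(truth, "study_truth"))
  state <- match.arg(state)
  dh <- if (state == "cis") truth$delta_h_cis else truth$delta_h_trans
  ds <- if (state == "cis") truth$delta_s_cis else truth$delta_s_trans
  ln_ka <- -dh / (phys_const$R * temperature) + ds / phys_const$R
  exp(-ln_ka)
}

#' @rdname true_kd
#' @export
true_tau <- function(truth, temperature, condition = c("P", "PL")) {
  stopifnot(inherits(truth, "study_truth"))
  condition <- match.arg(condition)
  dh <- if (condition == "P") truth$delta_h_act_p else truth$delta_h_act_pl
  a <- if (condition == "P") truth$prefactor_p else truth$prefactor_pl
  1 / (a * exp(-dh / (phys_const$R * temperature)))
}

#' Generate a complete multi-temperature study
#'
#' For every temperature in the ground truth, generates cis and trans
#' titrations (with `Kd(T)` from the van't Hoff law) and P and PL
#' relaxation traces (with `tau(T)` from the Arrhenius law). When
#' `cis_purity < 1`, the noiseless cis titration signal is the mixture
#' `purity * signal_cis + (1 - purity) * signal_trans`, emulating an
#' incompletely converted photostationary state. Per-dataset seeds are
#' derived deterministically from the master seed, so identical truth gives
#' a byte-identical dataset.
#'
#' @param truth a [study_truth].
#' @param titration_template list overriding titration defaults: `l0`,
#'   `p0_grid`, `signal_free`, `signal_bound`, `noise_sd`.
#' @param relaxation_template list overriding relaxation defaults:
#'   `a_start`, `a_end`, `n_times` (points per trace), `span_tau` (trace
#'   length in units of the true tau), `noise_sd`.
#' @return Object of class `study_data`: list with `titrations` and
#'   `relaxations` (flat lists of labelled series/traces) and `truth`.
#' @export
#' @examples
#' tr <- study_truth(130e3, entropy_from_anchor(130e3, 7e-6, 294.15),
#'                   -50e3, entropy_from_anchor(-50e3, 3.8e-6, 294.15),
#'                   89e3, prefactor_from_anchor(89e3, 2.68 * 3600, 294.15),
#'                   79e3, prefactor_from_anchor(79e3, 2.25 * 3600, 294.15))
#' study <- generate_study(tr)
#' length(study$titrations)  # 2 states x 4 temperatures
generate_study <- function(truth, titration_template = list(),
                           relaxation_template = list()) {
  stopifnot(inherits(truth, "study_truth"))
  tt <- utils::modifyList(
    list(l0 = 15e-6, p0_grid = seq(0, 50e-6, length.out = 12),
         signal_free = 1, signal_bound = 0, noise_sd = 0.02),
    titration_template)
  rt <- utils::modifyList(
    list(a_start = 0.2, a_end = 1.0, n_times = 50, span_tau = 3,
         noise_sd = 0.008),
    relaxation_template)
  titrations <- list()
  relaxations <- list()
  i <- 0L
  for (temp in truth$temperatures) {
    for (state in c("cis", "trans")) {
      i <- i + 1L
      sub_seed <- (truth$seed + 7919L * i) %% .Machine$integer.max
      kd <- true_kd(truth, temp, state)
      base <- titration_truth(kd_true = kd, l0 = tt$l0, p0_grid = tt$p0_grid,
                              signal_free = tt$signal_free,
                              signal_bound = tt$signal_bound,
                              noise_sd = 0, seed = sub_seed)
      series <- generate_titration(base, state = state, temperature = temp)
      sig <- series$points$signal
      if (state == "cis" && truth$cis_purity < 1) {
        kd_tr <- true_kd(truth, temp, "trans")
        trans_truth <- titration_truth(kd_true = kd_tr, l0 = tt$l0,
                                       p0_grid = tt$p0_grid,
                                       signal_free = tt$signal_free,
                                       signal_bound = tt$signal_bound,
                                       noise_sd = 0, seed = sub_seed)
        sig_tr <- generate_titration(trans_truth)$points$signal
        sig <- truth$cis_purity * sig + (1 - truth$cis_purity) * sig_tr
      }
      if (tt$noise_sd > 0) {
        sig <- sig + with_seed(sub_seed,
                               stats::rnorm(length(sig), 0, tt$noise_sd))
      }
      titrations[[sprintf("%s_%.2fK", state, temp)]] <-
        titration_series(p0 = tt$p0_grid, signal = sig, l0 = tt$l0,
                         temperature = temp, state = state)
    }
    for (condition in c("P", "PL")) {
      i <- i + 1L
      sub_seed <- (truth$seed + 7919L * i) %% .Machine$integer.max
      tau <- true_tau(truth, temp, condition)
      rtruth <- relaxation_truth(
        tau_true = tau, a_start = rt$a_start, a_end = rt$a_end,
        time_grid = seq(0, rt$span_tau * tau, length.out = rt$n_times),
        noise_sd = rt$noise_sd, seed = sub_seed)
      relaxations[[sprintf("%s_%.2fK", condition, temp)]] <-
        generate_relaxation(rtruth, condition = condition, temperature = temp)
    }
  }
  structure(list(titrations = titrations, relaxations = relaxations,
                 truth = truth),
            class = "study_data")
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf("Synthetic study: %d titrations, %d relaxation traces, %d temperatures\n",
              length(x$titrations), length(x$relaxations),
              length(x$truth$temperatures)))
  invisible(x)
}
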