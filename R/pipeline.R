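#' Run the full inference chain on a study
#'
#' Takes a complete study (e.g. from [generate_study()] or assembled from
#' CSV files) through every stage: per-temperature normalization of the raw
#' titrations (ligand-alone signal as 0% bound, plateau of the stronger
#' binder as 100%), Kd fits with the exact ligand-depletion isotherm,
#' mono-exponential fits of the relaxation traces, van't Hoff and Arrhenius
#' regressions, and assembly of the four-state cycle.
#'
#' The Kd fits float the saturation level as a nuisance scale
#' (`plateau = "fit"`), since a finite protein-concentration range never
#' quite reaches the plateau; set `plateau = "fixed"` to trust the
#' normalization references instead.
#'
#' @param study a `study_data` object: lists `titrations` (raw
#'   [titration_series]) and `relaxations` ([relaxation_trace]s).
#' @param delta_x anchor-distance change (m) passed to [assemble_cycle()];
#'   defaults to the study truth's value when present, else 3 Angstrom.
#' @param plateau passed to [fit_kd()].
#' @param weighted passed to [vant_hoff()] and [arrhenius()].
#' @return List of class `study_analysis`: `affinities`, `rates`,
#'   `vant_hoff` (list `cis`, `trans`), `arrhenius` (list `P`, `PL`), and
#'   `cycle` (a `cycle_energetics`).
#' @export
#' @examples
#' tr <- study_truth(130e3, entropy_from_anchor(130e3, 7e-6, 294.15),
#'                   -50e3, entropy_from_anchor(-50e3, 3.8e-6, 294.15),
#'                   89e3, prefactor_from_anchor(89e3, 2.68 * 3600, 294.15),
#'                   79e3, prefactor_from_anchor(79e3, 2.25 * 3600, 294.15))
#' res <- analyze_study(generate_study(tr))
#' res$cycle$ddh / 1000  # ~180 kJ/mol
analyze_study <- function(study, delta_x = NULL,
                          plateau = "fit", weighted = FALSE) {
  stopifnot(is.list(study), !is.null(study$titrations),
            !is.null(study$relaxations))
  if (is.null(delta_x)) {
    delta_x <- if (!is.null(study$truth$delta_x)) study$truth$delta_x else 3e-10
  }
  affinities <- fit_study_affinities(study$titrations, plateau = plateau)
  rates <- lapply(study$relaxations, fit_monoexponential)
  state_of <- vapply(affinities, `[[`, "", "state")
  cond_of <- vapply(rates, `[[`, "", "condition")
  vh <- list(cis = vant_hoff(unname(affinities[state_of == "cis"]), weighted = weighted),
             trans = vant_hoff(unname(affinities[state_of == "trans"]), weighted = weighted))
  arr <- list(P = arrhenius(unname(rates[cond_of == "P"]), weighted = weighted),
              PL = arrhenius(unname(rates[cond_of == "PL"]), weighted = weighted))
  cycle <- assemble_cycle(vh$cis, vh$trans, arr$P, arr$PL, delta_x = delta_x)
  structure(list(affinities = affinities, rates = rates,
                 vant_hoff = vh, arrhenius = arr, cycle = cycle),
            class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat("Study analysis\n")
  print(x$vant_hoff$cis); print(x$vant_hoff$trans)
  print(x$arrhenius$P); print(x$arrhenius$PL)
  print(x$cycle)
  invisible(x)
}

# internal: normalize raw titrations per temperature and fit every series.
# Zero reference: mean ligand-alone (p0 = 0) signal across the series of one
# temperature; full reference: plateau of the stronger binder (the series
# whose top-p0 signal lies farthest from the zero reference).
fit_study_affinities <- function(titrations, plateau = "fit") {
  temps <- vapply(titrations, `[[`, 0, "temperature")
  out <- vector("list", length(titrations))
  names(out) <- names(titrations)
  for (temp in unique(temps)) {
    idx <- which(temps == temp)
    group <- titrations[idx]
    zero_ref <- mean(unlist(lapply(group, function(s) {
      z <- s$points$signal[s$points$p0 == 0]
      if (length(z)) z else NULL
    })))
    if (!is.finite(zero_ref)) {
      stop(sprintf("no ligand-alone (p0 = 0) point at %.2f K; supply normalized data", temp),
           call. = FALSE)
    }
    plateaus <- vapply(group, plateau_signal, 0)
    full_ref <- plateaus[which.max(abs(plateaus - zero_ref))]
    for (j in idx) {
      out[[j]] <- fit_kd(normalize_titration(titrations[[j]], zero_ref, full_ref),
                         plateau = plateau)
    }
  }
  out
}
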