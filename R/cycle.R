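#' Assemble the four-state thermodynamic cycle
#'
#' Combines the two van't Hoff fits (binding enthalpy in the cis and trans
#' photoswitch states) and the two Arrhenius fits (isomerisation activation
#' enthalpy for free protein P and ligand-bound PL) into the four-state
#' cycle summary:
#' \describe{
#'   \item{`ddh`}{`dH_cis - dH_trans`, the difference in driving force for
#'     cis-to-trans isomerisation with and without ligand (J/mol).}
#'   \item{`ddh_act`}{`dH_act_PL - dH_act_P`, the ligand-induced change in
#'     the isomerisation barrier (J/mol).}
#'   \item{`phi`}{`(dH_cis + ddh_act) / dH_cis`, the fraction of the
#'     cis-state enthalpy shift inherited by the transition state (1 =
#'     fully cis-like, 0 = fully trans-like).}
#'   \item{`force`}{`ddh / (N_A * delta_x)`, the per-molecule allosteric
#'     force transmitted over the photoswitch anchor-distance change (N).}
#' }
#' Standard errors are first-order propagation assuming independence of the
#' four regressions (they use disjoint measurements); for the pure
#' differences this reduces to root-sum-square.
#'
#' @param vh_cis,vh_trans `vant_hoff_fit` objects for the cis and trans
#'   states.
#' @param arr_p,arr_pl `arrhenius_fit` objects for conditions P and PL.
#' @param delta_x photoswitch anchor-distance change (m); default 3 Angstrom.
#'   An external parameter (e.g. from MD), never computed here.
#' @return Object of class `cycle_energetics` with the four input
#'   enthalpies, the derived `ddh`, `ddh_act`, `phi`, `force`, `delta_x`,
#'   and an `se` list with a standard error for each.
#' @export
#' @examples
#' reproduce_table1()$cycle
assemble_cycle <- function(vh_cis, vh_trans, arr_p, arr_pl, delta_x = 3e-10) {
  stopifnot(inherits(vh_cis, "vant_hoff_fit"), inherits(vh_trans, "vant_hoff_fit"),
            inherits(arr_p, "arrhenius_fit"), inherits(arr_pl, "arrhenius_fit"))
  check_scalar(delta_x, "delta_x", positive = TRUE)
  dh_cis <- vh_cis$delta_h
  dh_trans <- vh_trans$delta_h
  dh_p <- arr_p$delta_h_act
  dh_pl <- arr_pl$delta_h_act
  ddh <- dh_cis - dh_trans
  ddh_act <- dh_pl - dh_p
  if (dh_cis == 0) {
    stop("phi undefined: cis-state binding enthalpy is zero", call. = FALSE)
  }
  phi <- phi_value(dh_cis, ddh_act)
  force <- allosteric_force(ddh, delta_x)

  se_cis <- vh_cis$delta_h_se
  se_trans <- vh_trans$delta_h_se
  se_p <- arr_p$delta_h_act_se
  se_pl <- arr_pl$delta_h_act_se
  se_ddh <- sqrt(se_cis^2 + se_trans^2)
  se_ddh_act <- sqrt(se_p^2 + se_pl^2)
  # phi = 1 + ddh_act/dh_cis; ddh_act independent of dh_cis
  se_phi <- sqrt((se_ddh_act / dh_cis)^2 + (ddh_act * se_cis / dh_cis^2)^2)
  se_force <- se_ddh / (phys_const$NA_avogadro * delta_x)

  structure(list(
    delta_h_cis = dh_cis, delta_h_trans = dh_trans,
    delta_h_act_p = dh_p, delta_h_act_pl = dh_pl,
    ddh = ddh, ddh_act = ddh_act, phi = phi,
    delta_x = delta_x, force = force,
    se = list(delta_h_cis = se_cis, delta_h_trans = se_trans,
              delta_h_act_p = se_p, delta_h_act_pl = se_pl,
              ddh = se_ddh, ddh_act = se_ddh_act,
              phi = se_phi, force = se_force)
  ), class = "cycle_energetics")
}

#' @export
print.cycle_energetics <- function(x, ...) {
  kj <- function(v) v / 1000
  cat("Four-state allosteric energetics\n")
  cat(sprintf("  dH_cis     = %7.1f +/- %.1f kJ/mol\n", kj(x$delta_h_cis), kj(x$se$delta_h_cis)))
  cat(sprintf("  dH_trans   = %7.1f +/- %.1f kJ/mol\n", kj(x$delta_h_trans), kj(x$se$delta_h_trans)))
  cat(sprintf("  dH_act(P)  = %7.1f +/- %.1f kJ/mol\n", kj(x$delta_h_act_p), kj(x$se$delta_h_act_p)))
  cat(sprintf("  dH_act(PL) = %7.1f +/- %.1f kJ/mol\n", kj(x$delta_h_act_pl), kj(x$se$delta_h_act_pl)))
  cat(sprintf("  ddH        = %7.1f +/- %.1f kJ/mol\n", kj(x$ddh), kj(x$se$ddh)))
  cat(sprintf("  ddH_act    = %7.1f +/- %.1f kJ/mol\n", kj(x$ddh_act), kj(x$se$ddh_act)))
  cat(sprintf("  phi        = %7.3f +/- %.3f\n", x$phi, x$se$phi))
  cat(sprintf("  force      = %s (dx = %.3g m)\n", format_force(x$force), x$delta_x))
  invisible(x)
}

#' Per-molecule allosteric force
#'
#' Converts a molar enthalpy difference acting over the photoswitch
#' anchor-distance change into a force per molecule:
#' `F = ddh / (N_A * delta_x)`. The sign of `ddh` is carried through.
#'
#' @param ddh enthalpy difference (J/mol).
#' @param delta_x distance change (m), > 0.
#' @return Force in Newton.
#' @export
#' @examples
#' allosteric_force(180e3, 3e-10) * 1e9  # ~1 nN
allosteric_force <- function(ddh, delta_x) {
  check_scalar(ddh, "ddh")
  check_scalar(delta_x, "delta_x", positive = TRUE)
  ddh / (phys_const$NA_avogadro * delta_x)
}

#' Format a force in convenient units
#'
#' @param force force in Newton.
#' @param digits significant digits.
#' @return Character scalar such as `"0.996 nN"` or `"16.6 pN"`.
#' @export
format_force <- function(force, digits = 3) {
  af <- abs(force)
  if (af >= 0.5e-9) {
    sprintf("%s nN", signif(force * 1e9, digits))
  } else if (af >= 0.5e-12) {
    sprintf("%s pN", signif(force * 1e12, digits))
  } else {
    sprintf("%s N", signif(force, digits))
  }
}

#' Transition-state cis-likeness (Phi value)
#'
#' Fraction of the cis-state binding-enthalpy shift that the isomerisation
#' transition state inherits: `phi = (dh_cis + ddh_act) / dh_cis`. A barrier
#' that shifts one-for-one with the cis state gives `phi = 1`; a barrier
#' pinned to the trans side gives `phi = 0`.
#'
#' @param delta_h_cis cis-state binding enthalpy (J/mol), nonzero.
#' @param ddh_act barrier change `dH_act_PL - dH_act_P` (J/mol).
#' @return Dimensionless phi.
#' @export
#' @examples
#' phi_value(130e3, -10e3)  # 0.923
phi_value <- function(delta_h_cis, ddh_act) {
  check_scalar(delta_h_cis, "delta_h_cis")
  check_scalar(ddh_act, "ddh_act")
  if (delta_h_cis == 0) {
    stop("phi undefined: delta_h_cis must be nonzero", call. = FALSE)
  }
  (delta_h_cis + ddh_act) / delta_h_cis
}

#' Affinity fold change between two dissociation constants
#'
#' `kd_a / kd_b`: how many fold more tightly state b binds than state a
#' (Kd and affinity are inversely related).
#'
#' @param kd_a,kd_b dissociation constants (same units), > 0.
#' @return Dimensionless fold change.
#' @export
#' @examples
#' affinity_ratio(14.2, 0.12)  # ~120-fold tighter cis binding at 40 C
affinity_ratio <- function(kd_a, kd_b) {
  check_scalar(kd_a, "kd_a", positive = TRUE)
  check_scalar(kd_b, "kd_b", positive = TRUE)
  kd_a / kd_b
}

#' Enthalpy offsets of the cycle states along the isomerisation coordinate
#'
#' Lays the four (or six) states of the cycle out as enthalpy offsets
#' relative to the free cis protein, for an energy-profile diagram:
#' `P_cis = 0`, `PL_cis = dH_cis`, `TS_P = dH_act_P`,
#' `TS_PL = dH_cis + dH_act_PL`. When an external isomerisation enthalpy of
#' the free protein `delta_h_iso_p` is supplied, the trans-side products are
#' added: `P_trans = delta_h_iso_p`,
#' `PL_trans = delta_h_iso_p + dH_trans`. Cycle closure holds by
#' construction: `(PL_trans - PL_cis) - (P_trans - P_cis) = -ddh` for any
#' `delta_h_iso_p`.
#'
#' @param cycle a [assemble_cycle()] result.
#' @param delta_h_iso_p optional isomerisation enthalpy of the free protein
#'   (J/mol); the cis-to-trans reaction enthalpy is not measurable from the
#'   binding/kinetics data alone, so it enters as an external parameter.
#' @return Object of class `energy_diagram`: a data.frame with columns
#'   `state` and `enthalpy` (J/mol, offset from `P_cis`).
#' @export
build_energy_diagram <- function(cycle, delta_h_iso_p = NULL) {
  stopifnot(inherits(cycle, "cycle_energetics"))
  states <- c("P_cis", "PL_cis", "TS_P", "TS_PL")
  enthalpy <- c(0, cycle$delta_h_cis, cycle$delta_h_act_p,
                cycle$delta_h_cis + cycle$delta_h_act_pl)
  if (!is.null(delta_h_iso_p)) {
    check_scalar(delta_h_iso_p, "delta_h_iso_p")
    states <- c(states, "P_trans", "PL_trans")
    enthalpy <- c(enthalpy, delta_h_iso_p, delta_h_iso_p + cycle$delta_h_trans)
  }
  structure(data.frame(state = states, enthalpy = enthalpy),
            class = c("energy_diagram", "data.frame"))
}
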