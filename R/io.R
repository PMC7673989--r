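#' The published temperature series of affinities and time constants
#'
#' The packaged fixture: dissociation constants of the peptide ligand in
#' the trans and cis photoswitch states (uM) and thermal cis-to-trans
#' isomerisation time constants of the free (P) and ligand-bound (PL)
#' protein (hours), with their standard errors, at 10/21/30/40 degC.
#'
#' @return data.frame with columns `temperature_c`, `kd_trans_um`,
#'   `kd_trans_se_um`, `kd_cis_um`, `kd_cis_se_um`, `tau_p_h`,
#'   `tau_p_se_h`, `tau_pl_h`, `tau_pl_se_h`.
#' @export
#' @examples
#' table1()
table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "allocycle",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

temperature_to_kelvin <- function(value, unit, where) {
  switch(as.character(unit),
         "K" = value,
         "C" = celsius_to_kelvin(value),
         stop(sprintf("%s: temperature_unit must be 'C' or 'K', got '%s'",
                      where, unit), call. = FALSE))
}

conc_to_molar <- function(value, unit, where) {
  switch(as.character(unit),
         "M" = value,
         "uM" = value * 1e-6,
         stop(sprintf("%s: conc_unit must be 'uM' or 'M', got '%s'",
                      where, unit), call. = FALSE))
}

time_to_seconds <- function(value, unit, where) {
  switch(as.character(unit),
         "s" = value,
         "h" = value * 3600,
         stop(sprintf("%s: time_unit must be 'h' or 's', got '%s'",
                      where, unit), call. = FALSE))
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read titration data from CSV
#'
#' Schema (one row per titration point): `state` (cis/trans/wild_type),
#' `temperature`, `temperature_unit` (C or K), `l0`, `conc_unit` (uM or M,
#' applies to `l0` and `p0`), `p0`, and exactly one of `signal` or
#' `fraction_bound`; an optional `replicate` column is carried along but
#' not interpreted. Units are mandatory tags, never assumed. Rows are
#' grouped by (state, temperature, l0) into series.
#'
#' @param path CSV file path.
#' @return A single [titration_series] if the file holds one group, else a
#'   named list of them.
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("state", "temperature", "temperature_unit",
                        "l0", "conc_unit", "p0"), path)
  has_signal <- "signal" %in% names(df)
  has_frac <- "fraction_bound" %in% names(df)
  if (has_signal == has_frac) {
    stop(sprintf("%s: need exactly one of 'signal' or 'fraction_bound'", path),
         call. = FALSE)
  }
  bad <- which(df$p0 < 0 | df$l0 <= 0)
  if (length(bad)) {
    stop(sprintf("%s: invalid concentration in row(s) %s (p0 >= 0, l0 > 0 required)",
                 path, paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  df$temperature_k <- mapply(temperature_to_kelvin, df$temperature,
                             df$temperature_unit, path)
  df$l0_m <- mapply(conc_to_molar, df$l0, df$conc_unit, path)
  df$p0_m <- mapply(conc_to_molar, df$p0, df$conc_unit, path)
  key <- interaction(df$state, df$temperature_k, df$l0_m, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    if (has_signal) {
      titration_series(p0 = g$p0_m, signal = g$signal, l0 = g$l0_m[1],
                       temperature = g$temperature_k[1], state = g$state[1])
    } else {
      titration_series(p0 = g$p0_m, fraction_bound = g$fraction_bound,
                       l0 = g$l0_m[1],
                       temperature = g$temperature_k[1], state = g$state[1])
    }
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Write a titration series to CSV
#'
#' Inverse of [read_titration_csv()]; concentrations written in M,
#' temperatures in K, with explicit unit columns.
#'
#' @param series a [titration_series] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  if (inherits(series, "titration_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    value_col <- if (s$normalized) "fraction_bound" else "signal"
    df <- data.frame(state = s$state, temperature = s$temperature,
                     temperature_unit = "K", l0 = s$l0, conc_unit = "M",
                     p0 = s$points$p0, stringsAsFactors = FALSE)
    df[[value_col]] <- s$points[[value_col]]
    df
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read relaxation traces from CSV
#'
#' Schema (one row per time point): `condition` (P or PL), `temperature`,
#' `temperature_unit` (C or K), `time`, `time_unit` (h or s),
#' `absorbance_370`. Rows are grouped by (condition, temperature).
#'
#' @param path CSV file path.
#' @return A single [relaxation_trace] if the file holds one group, else a
#'   named list of them.
#' @export
read_relaxation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("condition", "temperature", "temperature_unit",
                        "time", "time_unit", "absorbance_370"), path)
  bad <- which(df$time < 0)
  if (length(bad)) {
    stop(sprintf("%s: negative time in row(s) %s", path,
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  df$temperature_k <- mapply(temperature_to_kelvin, df$temperature,
                             df$temperature_unit, path)
  df$time_s <- mapply(time_to_seconds, df$time, df$time_unit, path)
  key <- interaction(df$condition, df$temperature_k, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_s), ]
    relaxation_trace(time = g$time_s, absorbance_370 = g$absorbance_370,
                     temperature = g$temperature_k[1], condition = g$condition[1])
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Write relaxation traces to CSV
#'
#' Inverse of [read_relaxation_csv()]; times written in seconds,
#' temperatures in K, with explicit unit columns.
#'
#' @param traces a [relaxation_trace] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_relaxation_csv <- function(traces, path) {
  if (inherits(traces, "relaxation_trace")) traces <- list(traces)
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(condition = tr$condition, temperature = tr$temperature,
               temperature_unit = "K", time = tr$samples$time,
               time_unit = "s", absorbance_370 = tr$samples$absorbance_370,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reproduce the headline energetics from the packaged temperature series
#'
#' Runs the whole upper half of the pipeline on the packaged fixture
#' ([table1()]): van't Hoff regressions of the cis and trans Kd columns,
#' Arrhenius regressions of the P and PL time-constant columns, and cycle
#' assembly with the given anchor-distance change. Also reports the
#' cis/trans affinity fold changes at the temperature extremes and the
#' Eyring frequency factor at 303.15 K for comparison with the fitted
#' prefactors.
#'
#' @param delta_x anchor-distance change (m); default 3 Angstrom.
#' @param weighted use the printed standard errors as regression weights
#'   (default `FALSE`: plain OLS).
#' @return List of class `table1_reproduction`: `vant_hoff` (cis, trans),
#'   `arrhenius` (P, PL), `cycle`, `fold_cis_over_trans_40C`,
#'   `fold_trans_over_cis_10C`, `eyring_303K`.
#' @export
#' @examples
#' reproduce_table1()
reproduce_table1 <- function(delta_x = 3e-10, weighted = FALSE) {
  tb <- table1()
  temp_k <- celsius_to_kelvin(tb$temperature_c)
  vh_cis <- vant_hoff(data.frame(temperature = temp_k,
                                 kd = tb$kd_cis_um * 1e-6,
                                 kd_se = tb$kd_cis_se_um * 1e-6),
                      state = "cis", weighted = weighted)
  vh_trans <- vant_hoff(data.frame(temperature = temp_k,
                                   kd = tb$kd_trans_um * 1e-6,
                                   kd_se = tb$kd_trans_se_um * 1e-6),
                        state = "trans", weighted = weighted)
  arr_p <- arrhenius(data.frame(temperature = temp_k,
                                tau = tb$tau_p_h * 3600,
                                tau_se = tb$tau_p_se_h * 3600),
                     condition = "P", weighted = weighted)
  arr_pl <- arrhenius(data.frame(temperature = temp_k,
                                 tau = tb$tau_pl_h * 3600,
                                 tau_se = tb$tau_pl_se_h * 3600),
                      condition = "PL", weighted = weighted)
  cycle <- assemble_cycle(vh_cis, vh_trans, arr_p, arr_pl, delta_x = delta_x)
  row40 <- tb[tb$temperature_c == 40, ]
  row10 <- tb[tb$temperature_c == 10, ]
  structure(list(
    vant_hoff = list(cis = vh_cis, trans = vh_trans),
    arrhenius = list(P = arr_p, PL = arr_pl),
    cycle = cycle,
    fold_cis_over_trans_40C = affinity_ratio(row40$kd_trans_um, row40$kd_cis_um),
    fold_trans_over_cis_10C = affinity_ratio(row10$kd_cis_um, row10$kd_trans_um),
    eyring_303K = eyring_prefactor(303.15)
  ), class = "table1_reproduction")
}

#' @export
print.table1_reproduction <- function(x, ...) {
  print(x$vant_hoff$cis); print(x$vant_hoff$trans)
  print(x$arrhenius$P); print(x$arrhenius$PL)
  print(x$cycle)
  cat(sprintf("  cis binds %.0f-fold tighter at 40 C; trans %.0f-fold tighter at 10 C\n",
              x$fold_cis_over_trans_40C, x$fold_trans_over_cis_10C))
  cat(sprintf("  Eyring kB*T/h at 303.15 K = %.3g 1/s\n", x$eyring_303K))
  invisible(x)
}

# sort all (nested) list entries by name for byte-deterministic JSON
sort_named <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    lapply(x, sort_named)
  } else x
}

#' Write a deterministic JSON energetics report
#'
#' Serializes a cycle (or a whole analysis, whose `$cycle` is used) to
#' JSON with sorted keys and 6-significant-digit floats, so identical
#' inputs yield byte-identical reports.
#'
#' @param energetics a `cycle_energetics`, `study_analysis` or
#'   `table1_reproduction`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(energetics, path) {
  extras <- list()
  if (inherits(energetics, c("study_analysis", "table1_reproduction"))) {
    full <- energetics
    energetics <- full$cycle
    extras <- list(
      vant_hoff = lapply(full$vant_hoff, function(f)
        f[c("state", "delta_h", "delta_h_se", "delta_s", "delta_s_se",
            "n_points")]),
      arrhenius = lapply(full$arrhenius, function(f)
        f[c("condition", "delta_h_act", "delta_h_act_se", "prefactor_a",
            "prefactor_log_se", "n_points")])
    )
  }
  stopifnot(inherits(energetics, "cycle_energetics"))
  report <- c(list(
    inputs = list(
      delta_h_cis = energetics$delta_h_cis,
      delta_h_trans = energetics$delta_h_trans,
      delta_h_act_p = energetics$delta_h_act_p,
      delta_h_act_pl = energetics$delta_h_act_pl,
      delta_x = energetics$delta_x,
      delta_x_provenance = "external parameter (anchor-distance change); not computed here"
    ),
    derived = list(ddh = energetics$ddh, ddh_act = energetics$ddh_act,
                   phi = energetics$phi, force = energetics$force),
    se = energetics$se,
    constants = phys_const
  ), extras)
  report <- sort_named(rapply(report, function(v)
    if (is.numeric(v)) signif(v, 6) else v, how = "replace"))
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  writeLines(json, path)
  invisible(path)
}
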