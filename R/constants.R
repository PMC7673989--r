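#' Physical constants used throughout the package
#'
#' CODATA 2018 exact values. All internal computation is in SI units:
#' mol/L for concentrations is the one deliberate exception (the standard
#' state for association constants is 1 mol/L).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{R}{molar gas constant, J/(mol K)}
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{h}{Planck constant, J s}
#'   \item{NA_avogadro}{Avogadro constant, 1/mol}
#' }
#' @export
#' @examples
#' phys_const$R
phys_const <- list(
  R = 8.314,
  kB = 1.380649e-23,
  h = 6.62607015e-34,
  NA_avogadro = 6.02214076e23
)

#' Convert Celsius to Kelvin
#'
#' @param temp_c temperature in degrees Celsius.
#' @return Temperature in Kelvin (`T(K) = T(degC) + 273.15`, exact).
#' @export
#' @examples
#' celsius_to_kelvin(c(10, 21, 30, 40))
celsius_to_kelvin <- function(temp_c) {
  temp_c + 273.15
}

# internal: check a scalar is a single finite number
check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}
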