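#' Physical constants and unit conversions
#'
#' Bundles the constants every thermodynamic operation in the package
#' depends on. Temperature is the only tunable: the default 298.15 K
#' reproduces the textbook one-proton one-electron Nernst slope of
#' -0.0592 V per pH unit.
#'
#' Internally all energies are carried in kJ/mol after a single
#' conversion from Hartree at ingestion (factor 2625.4996), so the
#' conversion factors live here and nowhere else.
#'
#' @param temperature Absolute temperature in Kelvin. Default 298.15.
#'
#' @return An object of class `thermo_constants`: a list with fields
#'   `R` (gas constant, J mol^-1 K^-1), `T` (K), `F` (Faraday constant,
#'   C mol^-1), `hartree_to_kj_per_mol`, and `hartree_to_ev`.
#' @examples
#' k <- thermo_constants()
#' nernst_slope(k) # ~0.0592 V/pH
#' @export
thermo_constants <- function(temperature = 298.15) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    abort("`temperature` must be a single positive number (Kelvin).")
  }
  structure(
    list(
      R = 8.314462618,
      T = temperature,
      F = 96485.33212,
      hartree_to_kj_per_mol = 2625.4996,
      hartree_to_ev = 27.211386245988
    ),
    class = "thermo_constants"
  )
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat("<thermo_constants>\n")
  cat(sprintf("  T = %.2f K, R = %.6f J/mol/K, F = %.2f C/mol\n", x$T, x$R, x$F))
  cat(sprintf("  RT ln10 = %.4f kJ/mol, Nernst slope = %.5f V/pH\n",
              rt_ln10(x), nernst_slope(x)))
  invisible(x)
}

#' RT ln(10) in kJ/mol
#'
#' The energy equivalent of one pKa unit (or one pH unit) at the
#' temperature carried by `k`. At 298.15 K this is 5.708 kJ/mol.
#'
#' @param k A [thermo_constants()] object.
#' @return A single number, kJ/mol.
#' @export
rt_ln10 <- function(k = thermo_constants()) {
  stopifnot(inherits(k, "thermo_constants"))
  k$R * k$T * log(10) / 1000
}

#' Nernst slope in V per pH unit
#'
#' `RT ln(10) / F`, the magnitude of the potential shift per pH unit
#' for a one-proton one-electron couple (0.0592 V at 298.15 K).
#'
#' @inheritParams rt_ln10
#' @return A single number, volts per pH unit.
#' @export
nernst_slope <- function(k = thermo_constants()) {
  stopifnot(inherits(k, "thermo_constants"))
  rt_ln10(k) * 1000 / k$F
}

# Hartree -> kJ/mol; the one and only conversion point.
hartree_to_kj <- function(x, k) x * k$hartree_to_kj_per_mol

# kJ/mol -> V for an n-electron step: E = dG / (n F).
kj_to_volts <- function(dg_kj, k, n_e = 1L) dg_kj * 1000 / (n_e * k$F)
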