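#' Physical constants and energy-unit conversions
#'
#' Conversion factors used throughout the package, derived from the 2018
#' CODATA values of the fundamental constants (exact by SI definition where
#' applicable): Planck constant h = 6.62607015e-34 J s, speed of light
#' c = 2.99792458e10 cm/s, Avogadro constant N_A = 6.02214076e23 1/mol, and
#' the thermochemical calorie 1 cal = 4.184 J.
#'
#' All energies inside the package are wavenumbers (cm^-1) relative to a
#' declared reference geometry unless stated otherwise. Frequencies follow
#' the natural-unit convention hbar = 1, so that the eigenvalue spacing of a
#' harmonic oscillator with Hessian eigenvalue lambda (cm^-2-like units) and
#' unit mass is sqrt(lambda) cm^-1; see [harmonic_frequencies()].
#'
#' @format A named numeric vector with elements:
#' \describe{
#'   \item{kcalmol_to_wavenumber}{cm^-1 per kcal/mol (chemical accuracy,
#'     1 kcal/mol, is about 350 cm^-1).}
#'   \item{hartree_to_wavenumber}{cm^-1 per hartree.}
#'   \item{ev_to_wavenumber}{cm^-1 per electronvolt.}
#'   \item{hessian_au_to_wavenumber}{converts the square root of a
#'     mass-weighted Hessian eigenvalue in hartree/(bohr^2 amu) to cm^-1;
#'     derived from E_h = 4.3597447222071e-18 J, a_0 = 5.29177210903e-11 m,
#'     u = 1.66053906660e-27 kg.}
#' }
#' @export
#' @examples
#' round(unit_constants[["kcalmol_to_wavenumber"]] / 10) * 10  # ~ 350
unit_constants <- c(
  # 4184 J/mol / (N_A h c):  4184 / 6.02214076e23 / (6.62607015e-34 * 2.99792458e10)
  kcalmol_to_wavenumber = 4184 / 6.02214076e23 / (6.62607015e-34 * 2.99792458e10),
  hartree_to_wavenumber = 219474.6313632,
  ev_to_wavenumber      = 8065.543937,
  # sqrt(E_h / (a_0^2 u)) / (2 pi c), in cm^-1
  hessian_au_to_wavenumber =
    sqrt(4.3597447222071e-18 / (5.29177210903e-11^2 * 1.66053906660e-27)) /
      (2 * pi * 2.99792458e10),
  # natural time unit of the hbar = 1, energy-in-cm^-1 convention is
  # 1 / (2 pi c [cm/s]); one femtosecond in those units:
  fs_to_natural_time = 2 * pi * 2.99792458e10 * 1e-15
)

#' Convert an energy value between supported units
#'
#' @param x numeric energy value(s).
#' @param from,to one of `"wavenumber"`, `"kcalmol"`, `"hartree"`, `"ev"`.
#' @return numeric vector in the target unit.
#' @export
#' @examples
#' convert_energy(1, "kcalmol", "wavenumber")  # ~ 349.76
convert_energy <- function(x, from, to) {
  to_wn <- c(wavenumber = 1,
             kcalmol = unname(unit_constants[["kcalmol_to_wavenumber"]]),
             hartree = unname(unit_constants[["hartree_to_wavenumber"]]),
             ev = unname(unit_constants[["ev_to_wavenumber"]]))
  from <- match.arg(from, names(to_wn))
  to <- match.arg(to, names(to_wn))
  x * to_wn[[from]] / to_wn[[to]]
}
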