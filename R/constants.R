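# Physical constants (CODATA 2018; SI-exact where the SI defines them)
.const <- list(
  R          = 8.31446261815324,   # gas constant, J mol^-1 K^-1
  kB         = 1.380649e-23,       # Boltzmann constant, J K^-1
  h          = 6.62607015e-34,     # Planck constant, J s
  N_A        = 6.02214076e23,      # Avogadro number, mol^-1
  c_cm       = 2.99792458e10,      # speed of light, cm s^-1
  hartree_kj = 2625.499639,        # kJ mol^-1 per hartree
  amu_kg     = 1.66053906660e-27,  # kg per unified atomic mass unit
  angstrom_m = 1e-10               # m per angstrom
)

# Standard atomic weights (CIAAW 2021 conventional values), u.
# Abundance-weighted, not single-isotope, matching common thermochemistry codes.
.atomic_masses <- c(
  H = 1.008, He = 4.002602,
  Li = 6.94, Be = 9.0121831, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998403162, Ne = 20.1797,
  Na = 22.98976928, Mg = 24.305, Al = 26.9815384, Si = 28.085, P = 30.973761998,
  S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.0983, Ca = 40.078, Sc = 44.955907, Ti = 47.867, V = 50.9415,
  Cr = 51.9961, Mn = 54.938043, Fe = 55.845, Co = 58.933194, Ni = 58.6934,
  Cu = 63.546, Zn = 65.38, Ga = 69.723, Ge = 72.630, As = 74.921595,
  Se = 78.971, Br = 79.904, Kr = 83.798,
  Rb = 85.4678, Sr = 87.62, Y = 88.905838, Zr = 91.222, Nb = 92.90637,
  Mo = 95.95, Ru = 101.07, Rh = 102.90549, Pd = 106.42, Ag = 107.8682,
  Cd = 112.414, In = 114.818, Sn = 118.710, Sb = 121.760, Te = 127.60,
  I = 126.90447, Xe = 131.293,
  Cs = 132.90545196, Ba = 137.327, La = 138.90547, W = 183.84, Re = 186.207,
  Os = 190.23, Ir = 192.217, Pt = 195.084, Au = 196.966570, Hg = 200.592,
  Tl = 204.38, Pb = 207.2, Bi = 208.98040
)

#' Molar mass from element symbols
#'
#' Sums standard atomic weights (abundance-weighted, not single-isotope) over
#' the supplied element symbols and returns the molar mass in kg/mol, the unit
#' expected by [translational_entropy()].
#'
#' @param element_symbols Character vector of element symbols (e.g. `c("O","H","H")`).
#' @return Molar mass in kg/mol (single numeric).
#' @examples
#' molar_mass(c("O", "H", "H"))  # water, ~0.018 kg/mol
#' @export
molar_mass <- function(element_symbols) {
  m <- .atomic_masses[element_symbols]
  if (anyNA(m)) {
    bad <- unique(element_symbols[is.na(m)])
    abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  }
  sum(m) * 1e-3
}
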