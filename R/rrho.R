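#' Ideal-gas translational entropy (Sackur-Tetrode)
#'
#' @param molar_mass Molar mass in kg/mol (see [molar_mass()]).
#' @param temperature Temperature in K.
#' @param pressure Pressure in Pa.
#' @return Translational entropy in J mol^-1 K^-1.
#' @details Doubling the pressure at fixed temperature lowers the entropy by
#'   exactly `R * log(2)`; the default state used throughout the package is
#'   298.15 K and 101325 Pa with no concentration correction.
#' @export
translational_entropy <- function(molar_mass, temperature = 298.15,
                                  pressure = 101325) {
  if (molar_mass <= 0 || temperature <= 0 || pressure <= 0) {
    abort("molar_mass, temperature and pressure must all be positive")
  }
  m <- molar_mass / .const$N_A
  q <- (2 * pi * m * .const$kB * temperature / .const$h^2)^1.5 *
    .const$kB * temperature / pressure
  .const$R * (log(q) + 2.5)
}

# principal moments of inertia in amu A^2, ascending
.principal_moments <- function(element_symbols, coordinates) {
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != length(element_symbols)) {
    abort("coordinate count does not match element count")
  }
  m <- .atomic_masses[element_symbols]
  if (anyNA(m)) {
    abort(paste0("unknown element symbol(s): ",
                 paste(unique(element_symbols[is.na(m)]), collapse = ", ")))
  }
  com <- colSums(coordinates * m) / sum(m)
  xyz <- sweep(coordinates, 2, com)
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  I <- matrix(c(
    sum(m * (y^2 + z^2)), -sum(m * x * y),       -sum(m * x * z),
    -sum(m * x * y),       sum(m * (x^2 + z^2)), -sum(m * y * z),
    -sum(m * x * z),      -sum(m * y * z),        sum(m * (x^2 + y^2))
  ), 3, 3)
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
}

#' Rigid-rotor rotational entropy
#'
#' Computes the classical rigid-rotor entropy from the principal moments of
#' inertia of the supplied geometry.  Species whose smallest principal moment
#' falls below `linear_tol` are treated as linear rotors; single atoms have no
#' rotational entropy and return 0.
#'
#' @param element_symbols Element symbols, one per atom.
#' @param coordinates Cartesian coordinates in Angstrom (one row per atom).
#' @param symmetry_number Rotational symmetry number sigma (positive integer);
#'   never inferred from the geometry, always user-supplied.
#' @param temperature Temperature in K.
#' @param linear_tol Linearity threshold on the smallest principal moment in
#'   amu A^2 (default 1e-3).
#' @return Rotational entropy in J mol^-1 K^-1.
#' @export
rotational_entropy <- function(element_symbols, coordinates, symmetry_number = 1,
                               temperature = 298.15, linear_tol = 1e-3) {
  if (symmetry_number < 1) abort("symmetry_number must be >= 1")
  if (temperature <= 0) abort("temperature must be positive")
  if (length(element_symbols) == 1L) return(0)
  I_amu <- .principal_moments(element_symbols, coordinates)
  if (all(I_amu < linear_tol)) abort("all atoms coincident: inertia tensor is singular")
  I_si <- I_amu * .const$amu_kg * .const$angstrom_m^2
  hbar <- .const$h / (2 * pi)
  if (I_amu[1] < linear_tol) {
    # linear rotor: one rotational constant from the two (equal) large moments
    I_lin <- mean(I_si[2:3])
    theta <- hbar^2 / (2 * I_lin * .const$kB)
    .const$R * (1 + log(temperature / (symmetry_number * theta)))
  } else {
    theta <- hbar^2 / (2 * I_si * .const$kB)
    q <- sqrt(pi) / symmetry_number * sqrt(temperature^3 / prod(theta))
    .const$R * (1.5 + log(q))
  }
}

#' Quasi-harmonic vibrational entropy with low-frequency raising
#'
#' Harmonic-oscillator vibrational entropy summed over modes, with every
#' frequency below `raising_cutoff` replaced by the cutoff before evaluation.
#' Raising unreliably low harmonic frequencies to 100 cm^-1 is the standard
#' quasi-harmonic remedy for the divergence of the harmonic entropy term as a
#' frequency approaches zero; set `raising_cutoff = 0` for the plain harmonic
#' result.
#'
#' @param frequencies Wavenumbers in cm^-1; all must be positive (negative
#'   values conventionally encode imaginary modes).
#' @param temperature Temperature in K.
#' @param raising_cutoff Raising threshold in cm^-1 (default 100).
#' @param discard_imaginary If `TRUE`, non-positive frequencies are dropped
#'   with a warning instead of raising an error.
#' @return Vibrational entropy in J mol^-1 K^-1 (0 for an empty list).
#' @export
vibrational_entropy <- function(frequencies, temperature = 298.15,
                                raising_cutoff = 100, discard_imaginary = FALSE) {
  if (temperature <= 0) abort("temperature must be positive")
  if (length(frequencies) == 0L) return(0)
  if (!all(is.finite(frequencies))) abort("frequencies must be finite")
  bad <- frequencies <= 0
  if (any(bad)) {
    if (discard_imaginary) {
      warn(sprintf("discarding %d imaginary/zero mode(s)", sum(bad)))
      frequencies <- frequencies[!bad]
      if (length(frequencies) == 0L) return(0)
    } else {
      abort(sprintf("%d imaginary/zero frequencies; rerun with discard_imaginary = TRUE to drop them",
                    sum(bad)))
    }
  }
  nu <- pmax(frequencies, raising_cutoff)
  x <- .const$h * .const$c_cm * nu / (.const$kB * temperature)
  sum(.const$R * (x / expm1(x) - log(-expm1(-x))))
}

#' Electronic entropy from the spin multiplicity
#'
#' `R * log(multiplicity)`, assuming the ground state is the only thermally
#' accessible electronic state.
#'
#' @param multiplicity Spin multiplicity 2S+1 (>= 1).
#' @return Electronic entropy in J mol^-1 K^-1.
#' @export
electronic_entropy <- function(multiplicity) {
  if (multiplicity < 1) abort("multiplicity must be >= 1")
  .const$R * log(multiplicity)
}

#' Full RRHO entropy decomposition for one species
#'
#' Combines the translational, rotational, quasi-harmonic vibrational and
#' electronic entropy of a species at a given temperature and pressure into a
#' one-row tibble.  This is the quantity needed at the two anchoring points of
#' the entropy model: the bound complex and the infinitely separated fragments.
#'
#' @inheritParams rotational_entropy
#' @inheritParams vibrational_entropy
#' @param frequencies Harmonic wavenumbers in cm^-1 (at most 3N-6 for a
#'   nonlinear, 3N-5 for a linear N-atom species).
#' @param multiplicity Spin multiplicity 2S+1.
#' @param pressure Pressure in Pa.
#' @param label Species label carried into reports.
#' @return A one-row tibble of class `thermo_state` with columns
#'   `species_label`, `temperature`, `pressure`, `s_trans`, `s_rot`, `s_vib`,
#'   `s_elec`, `s_total` (all J mol^-1 K^-1) and `minus_T_S` (-T*S in kJ/mol).
#' @examples
#' ar <- species_entropy("Ar", matrix(0, 1, 3), numeric(0), label = "argon")
#' ar$s_trans  # Sackur-Tetrode value, ~154.8 J/mol/K
#' @export
species_entropy <- function(element_symbols, coordinates, frequencies,
                            multiplicity = 1, symmetry_number = 1,
                            temperature = 298.15, pressure = 101325,
                            raising_cutoff = 100, discard_imaginary = FALSE,
                            label = "species") {
  coordinates <- as.matrix(coordinates)
  n <- length(element_symbols)
  if (nrow(coordinates) != n) abort("coordinate count does not match element count")
  s_tr <- translational_entropy(molar_mass(element_symbols), temperature, pressure)
  if (n == 1L) {
    s_rot <- 0
    max_modes <- 0L
  } else {
    s_rot <- rotational_entropy(element_symbols, coordinates, symmetry_number,
                                temperature)
    is_lin <- .principal_moments(element_symbols, coordinates)[1] < 1e-3
    max_modes <- if (is_lin) 3L * n - 5L else 3L * n - 6L
  }
  if (length(frequencies) > max_modes) {
    abort(sprintf("%d frequencies supplied but a %d-atom %s species has at most %d modes",
                  length(frequencies), n,
                  if (n == 1L) "atomic" else "molecular", max_modes))
  }
  s_vib <- vibrational_entropy(frequencies, temperature, raising_cutoff,
                               discard_imaginary)
  s_el <- electronic_entropy(multiplicity)
  s_tot <- s_tr + s_rot + s_vib + s_el
  out <- tibble(
    species_label = label, temperature = temperature, pressure = pressure,
    s_trans = s_tr, s_rot = s_rot, s_vib = s_vib, s_elec = s_el,
    s_total = s_tot, minus_T_S = -temperature * s_tot / 1000
  )
  class(out) <- c("thermo_state", class(out))
  out
}

#' Entropy amplitude of a dissociation
#'
#' The total entropy change of splitting the complex AB into fragments A and B,
#' `delta_s_diss = S(A) + S(B) - S(AB)`, and the corresponding free-energy
#' amplitude `-T * delta_s_diss` in kJ/mol.  The amplitude is the asymptotic
#' value of the sigmoid entropy model: for a typical small-molecule
#' dissociation at room temperature it is a few tens of kJ/mol in magnitude and
#' negative, because dissociation gains entropy.
#'
#' @param complex_state,fragment_a,fragment_b One-row `thermo_state` tibbles
#'   from [species_entropy()], all at identical temperature and pressure.
#' @return A one-row tibble of class `entropy_amplitude` with columns
#'   `delta_s_diss` (J mol^-1 K^-1), `amplitude` (kJ/mol) and `temperature` (K).
#' @export
entropy_amplitude <- function(complex_state, fragment_a, fragment_b) {
  states <- list(complex_state, fragment_a, fragment_b)
  if (!all(vapply(states, inherits, logical(1), "thermo_state"))) {
    abort("all three inputs must be thermo_state objects from species_entropy()")
  }
  Ts <- vapply(states, function(s) s$temperature, numeric(1))
  Ps <- vapply(states, function(s) s$pressure, numeric(1))
  if (diff(range(Ts)) > 1e-9 * max(Ts) || diff(range(Ps)) > 1e-9 * max(Ps)) {
    abort("complex and fragments must share the same temperature and pressure")
  }
  ds <- fragment_a$s_total + fragment_b$s_total - complex_state$s_total
  out <- tibble(
    delta_s_diss = ds,
    amplitude = -Ts[1] * ds / 1000,
    temperature = Ts[1]
  )
  class(out) <- c("entropy_amplitude", class(out))
  out
}

#' @method tidy thermo_state
#' @export
tidy.thermo_state <- function(x, ...) {
  tibble(
    component = c("translational", "rotational", "vibrational", "electronic", "total"),
    entropy = c(x$s_trans, x$s_rot, x$s_vib, x$s_elec, x$s_total)
  )
}

#' @method glance thermo_state
#' @export
glance.thermo_state <- function(x, ...) as_tibble(unclass(x))
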