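#' Define a synthetic dissociation case with known ground truth
#'
#' Builds a fully specified synthetic dissociation: a Morse electronic curve,
#' an exponentially decaying descriptor (on the normalized scale, i.e. valued
#' ~1 at the scan start and decaying towards 0), an entropy amplitude, and
#' optional i.i.d. Gaussian noise on both series.  The defaults emulate the
#' water-dimer study conditions: a hydrogen-bond-like well of 20 kJ/mol at
#' 1.95 Angstrom scanned to 6 Angstrom in 0.05 Angstrom steps, an IBSI-like
#' descriptor decay of 1.3 1/Angstrom, and the canonical ~35 kJ/mol entropy
#' amplitude of a two-fragment dissociation at room temperature.
#'
#' @param well_depth True Morse well depth in kJ/mol.
#' @param decay True Morse decay in 1/Angstrom.
#' @param r_eq True equilibrium distance in Angstrom.
#' @param k_desc True descriptor decay constant in 1/Angstrom.
#' @param d0 True descriptor amplitude; defaults to `exp(k_desc * r_start)` so
#'   the descriptor equals 1 at the scan start, mirroring a min-max-normalized
#'   bond order.
#' @param amplitude True entropy amplitude `-T dS_diss` in kJ/mol (negative for
#'   an entropy-gaining dissociation).
#' @param noise_energy Gaussian noise s.d. on energies, kJ/mol.
#' @param noise_descriptor Gaussian noise s.d. on descriptor values.
#' @param r_start,r_end,step Scan grid in Angstrom.
#' @param seed Integer seed; all generated noise is a deterministic function
#'   of it.
#' @return An object of class `synthetic_case`.
#' @export
synthetic_case <- function(well_depth = 20, decay = 2, r_eq = 1.95,
                           k_desc = 1.3, d0 = NULL, amplitude = -35,
                           noise_energy = 0, noise_descriptor = 0,
                           r_start = 1.95, r_end = 6, step = 0.05,
                           seed = 1L) {
  if (step <= 0) abort("step must be positive")
  if (r_start < r_eq - 0.2) abort("r_start must not lie more than 0.2 A below r_eq")
  if (noise_energy < 0 || noise_descriptor < 0) abort("noise s.d. must be >= 0")
  if (well_depth <= 0 || decay <= 0 || k_desc <= 0) {
    abort("well_depth, decay and k_desc must be positive")
  }
  d0 <- d0 %||% exp(k_desc * r_start)
  structure(list(
    well_depth = well_depth, decay = decay, r_eq = r_eq,
    k_desc = k_desc, d0 = d0, amplitude = amplitude,
    noise_energy = noise_energy, noise_descriptor = noise_descriptor,
    r_start = r_start, r_end = r_end, step = step, seed = as.integer(seed)
  ), class = "synthetic_case")
}

.case_grid <- function(case) seq(case$r_start, case$r_end, by = case$step)

#' Generate the energy scan of a synthetic case
#'
#' Evaluates the true Morse curve on the case grid and adds seeded Gaussian
#' noise; with zero noise the energies equal the Morse closed form exactly.
#'
#' @param case A [synthetic_case()].
#' @return A [dissociation_scan()].
#' @export
gen_scan <- function(case) {
  stopifnot(inherits(case, "synthetic_case"))
  r <- .case_grid(case)
  e <- morse_energy(r, case$well_depth, case$decay, case$r_eq)
  if (case$noise_energy > 0) {
    e <- e + withr::with_seed(case$seed, rnorm(length(r), 0, case$noise_energy))
  }
  dissociation_scan(r, e, label = sprintf("synthetic scan (seed %d)", case$seed))
}

#' Generate the descriptor series of a synthetic case
#'
#' `d0 * exp(-k_desc * r)` on the case grid plus seeded Gaussian noise,
#' clipped at zero (descriptor values cannot be negative).  The noise stream
#' is independent of the energy noise of [gen_scan()].
#'
#' @param case A [synthetic_case()].
#' @return A [descriptor_series()] with raw values only.
#' @export
gen_descriptor <- function(case) {
  stopifnot(inherits(case, "synthetic_case"))
  r <- .case_grid(case)
  v <- case$d0 * exp(-case$k_desc * r)
  if (case$noise_descriptor > 0) {
    v <- v + withr::with_seed(case$seed + 1L,
                              rnorm(length(r), 0, case$noise_descriptor))
  }
  descriptor_series(r, pmax(v, 0), name = sprintf("synthetic (seed %d)", case$seed))
}

#' Analytic brute-force barrier oracle for a synthetic case
#'
#' Composes the free-energy curve exactly from the case's true parameters —
#' true Morse curve, cleavage distance from the true descriptor including the
#' exact min-max normalization applied on the case grid, sigmoid at the given
#' steepness — and maximizes it by brute force on a dense grid.  This is an
#' independent code path against which the fitting pipeline is judged; it
#' performs no fitting and no refinement.
#'
#' @param case A [synthetic_case()].
#' @param gamma_cleave Slope cutoff on the normalized descriptor.
#' @param k_sig Sigmoid steepness in 1/Angstrom (take the tuned value from the
#'   pipeline when comparing end to end).
#' @param grid_step Oracle grid resolution in Angstrom (default 1e-4).
#' @param tol_barrier Barrier height tolerance in kJ/mol (default 0.01).
#' @return A one-row tibble with `no_barrier`, `r_ts`, `barrier_dissociation`,
#'   `barrier_association` and `r_cleave`; barriers are `NA` when no interior
#'   maximum exceeds the references.
#' @export
analytic_barrier <- function(case, gamma_cleave = 0.02, k_sig = 10,
                             grid_step = 1e-4, tol_barrier = 0.01) {
  stopifnot(inherits(case, "synthetic_case"))
  grid0 <- .case_grid(case)
  d <- case$d0 * exp(-case$k_desc * grid0)
  span <- max(d) - min(d)
  # normalized descriptor slope: k * d0 * exp(-k r) / (max - min)
  slope_start <- case$k_desc * case$d0 * exp(-case$k_desc * case$r_start) / span
  if (gamma_cleave >= slope_start) {
    abort("gamma_cleave exceeds the normalized descriptor slope at the scan start")
  }
  rc <- log(case$k_desc * case$d0 / (span * gamma_cleave)) / case$k_desc
  r <- seq(case$r_eq, max(case$r_end, rc + 10 / k_sig), by = grid_step)
  g <- morse_energy(r, case$well_depth, case$decay, case$r_eq) +
    case$amplitude / (1 + exp(-k_sig * (r - rc)))
  i <- which.max(g)
  none <- tibble(no_barrier = TRUE, r_ts = NA_real_,
                 barrier_dissociation = NA_real_,
                 barrier_association = NA_real_, r_cleave = rc)
  if (i == 1L || i == length(g)) return(none)
  bd <- g[i] - g[1]
  ba <- g[i] - case$amplitude
  if (bd <= tol_barrier && ba <= tol_barrier) return(none)
  tibble(no_barrier = FALSE, r_ts = r[i], barrier_dissociation = bd,
         barrier_association = ba, r_cleave = rc)
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf(
    "<synthetic_case: De %.3g kJ/mol, a %.3g 1/A, r_eq %.3g A, k_desc %.3g 1/A, amplitude %.3g kJ/mol,\n  grid %.3g-%.3g A step %.3g, noise (E %.3g, D %.3g), seed %d>\n",
    x$well_depth, x$decay, x$r_eq, x$k_desc, x$amplitude,
    x$r_start, x$r_end, x$step, x$noise_energy, x$noise_descriptor, x$seed))
  invisible(x)
}
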