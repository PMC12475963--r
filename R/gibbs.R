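#' Assemble the Gibbs free-energy curve
#'
#' Pointwise sum of the fitted Morse electronic energy and the sigmoid entropy
#' model on a distance grid: `dG(r) = dE_morse(r) + (-T dS_sigmoid(r))`.  The
#' sigmoid is used literally by default, so its (small) residual value at the
#' equilibrium distance is part of the curve and is reported; setting
#' `offset_at_req = TRUE` subtracts that residual so the curve starts exactly
#' at the Morse value.
#'
#' @param morse A [fit_morse()] result.
#' @param sigmoid An [sigmoid_model()].
#' @param grid Distance grid in Angstrom; must start at (or before) the Morse
#'   equilibrium distance.
#' @param offset_at_req Subtract the sigmoid value at `r_eq` from the whole
#'   curve (default `FALSE`).
#' @return An object of class `free_energy_result` holding the curve (a tibble
#'   with columns `r` and `delta_g`), the two component models, the large-`r`
#'   asymptote, and empty barrier fields to be filled by [find_barrier()].
#' @export
assemble_gibbs <- function(morse, sigmoid, grid, offset_at_req = FALSE) {
  stopifnot(inherits(morse, "morse_fit"), inherits(sigmoid, "entropy_sigmoid"))
  grid <- sort(grid)
  if (length(grid) < 3L) abort("grid needs at least 3 points")
  if (grid[1] > morse$r_eq + 1e-9) {
    abort(sprintf("grid does not cover r_eq: starts at %g A but r_eq = %g A",
                  grid[1], morse$r_eq))
  }
  sig_at_req <- entropy_sigmoid(morse$r_eq, sigmoid)
  offset <- if (offset_at_req) sig_at_req else 0
  dg <- predict(morse, grid) + entropy_sigmoid(grid, sigmoid) - offset
  structure(list(
    curve = tibble(r = grid, delta_g = dg),
    morse = morse, sigmoid = sigmoid,
    offset_at_req = offset_at_req, offset = offset,
    residual_at_req = sig_at_req,
    asymptote = sigmoid$amplitude - offset,
    k_sig_final = sigmoid$k_sig,
    r_ts = NA_real_, i_ts = NA_integer_,
    barrier_dissociation = NA_real_, barrier_association = NA_real_,
    no_barrier = NA
  ), class = "free_energy_result")
}

# model-based curve value at arbitrary r (same composition as the stored curve)
.eval_curve <- function(result, r) {
  predict(result$morse, r) + entropy_sigmoid(r, result$sigmoid) - result$offset
}

#' Locate the transition state and extract barriers
#'
#' Finds the global interior maximum of the assembled free-energy curve beyond
#' the equilibrium distance by grid scan with three-point parabolic refinement.
#' The dissociation barrier is referenced to the curve value at `r_eq`; the
#' association barrier to the large-`r` asymptote (the fully separated
#' fragments, set to the entropy amplitude).  If the interior maximum exceeds
#' neither reference by more than `tol_barrier`, the result is flagged
#' `no_barrier` — a valid outcome, not an error.
#'
#' @param result A `free_energy_result` from [assemble_gibbs()].
#' @param tol_barrier Minimum height in kJ/mol for a maximum to count as a
#'   barrier (default 0.01).
#' @return The result with `r_ts`, `barrier_dissociation`,
#'   `barrier_association` and `no_barrier` filled in.
#' @export
find_barrier <- function(result, tol_barrier = 0.01) {
  stopifnot(inherits(result, "free_energy_result"))
  g <- result$curve$delta_g
  r <- result$curve$r
  n <- length(g)
  interior <- which(g[2:(n - 1)] >= g[1:(n - 2)] & g[2:(n - 1)] >= g[3:n]) + 1L
  g_req <- .eval_curve(result, result$morse$r_eq)
  if (length(interior) == 0L) {
    result$no_barrier <- TRUE
    return(result)
  }
  i <- interior[which.max(g[interior])]
  # three-point parabolic refinement for sub-grid placement of the maximum
  denom <- g[i - 1] - 2 * g[i] + g[i + 1]
  r_ts <- if (abs(denom) > .Machine$double.eps * max(abs(g[i]), 1)) {
    r[i] + 0.5 * (r[i] - r[i - 1]) * (g[i - 1] - g[i + 1]) / denom
  } else r[i]
  r_ts <- min(max(r_ts, r[i - 1]), r[i + 1])
  g_ts <- .eval_curve(result, r_ts)
  if (g_ts < g[i]) {
    g_ts <- g[i]
    r_ts <- r[i]
  }
  bd <- g_ts - g_req
  ba <- g_ts - result$asymptote
  if (bd <= tol_barrier && ba <= tol_barrier) {
    result$no_barrier <- TRUE
    return(result)
  }
  result$no_barrier <- FALSE
  result$r_ts <- r_ts
  result$i_ts <- i
  result$barrier_dissociation <- bd
  result$barrier_association <- ba
  result
}

#' Depth of any free-energy dip beyond the transition state
#'
#' Scans the stored curve from the transition state outward (the large-`r`
#' asymptote is appended as the limiting point) and returns the largest rise
#' above the running minimum — the depth of the deepest local minimum after
#' the transition state.  Zero means the curve decays monotonically to the
#' separated fragments, the physically expected shape; the steepness tuning of
#' [tune_steepness()] drives this quantity below its tolerance.
#'
#' @param result A `free_energy_result` with barriers located.
#' @return Dip depth in kJ/mol (0 when there is no transition state).
#' @export
post_ts_dip <- function(result) {
  stopifnot(inherits(result, "free_energy_result"))
  if (isTRUE(result$no_barrier) || is.na(result$i_ts)) return(0)
  g <- result$curve$delta_g
  seg <- c(g[seq(result$i_ts, length(g))], result$asymptote)
  max(seg - cummin(seg))
}

#' Tune the sigmoid steepness until no minimum survives beyond the TS
#'
#' A steep entropy onset can leave an unphysical free-energy minimum between
#' the transition state and the separated fragments.  Starting from `k_start`,
#' the steepness is multiplied by `shrink` until the assembled curve, scanned
#' at `grid_step` resolution, no longer has a post-TS minimum deeper than
#' `tol_min`; the first (largest) steepness that passes is returned.  If no
#' steepness yields a transition state at all, the no-barrier result at
#' `k_start` is returned.
#'
#' @param morse A [fit_morse()] result.
#' @param amplitude Entropy amplitude in kJ/mol (or an [entropy_amplitude()]).
#' @param r_cleave Cleavage distance in Angstrom (or a [cleavage_distance()]).
#' @param k_start Initial steepness in 1/Angstrom (default 10).
#' @param shrink Multiplicative decrease per iteration (default 0.9).
#' @param k_floor Smallest admissible steepness; reaching it without success
#'   is an error (default 0.1).
#' @param grid_step Curve resolution in Angstrom (default 1e-3).
#' @param tol_min Depth tolerance for a post-TS minimum in kJ/mol (default 0.01).
#' @param tol_barrier Passed to [find_barrier()].
#' @param r_max Right end of the evaluation window; defaults to the scan end,
#'   and is always extended to at least `r_cleave + 10 / k_sig` so the sigmoid
#'   is saturated within the window.
#' @param offset_at_req Passed to [assemble_gibbs()].
#' @return A `free_energy_result` with barriers located and `k_sig_final` set
#'   to the tuned steepness.
#' @export
tune_steepness <- function(morse, amplitude, r_cleave,
                           k_start = 10, shrink = 0.9, k_floor = 0.1,
                           grid_step = 1e-3, tol_min = 0.01, tol_barrier = 0.01,
                           r_max = NULL, offset_at_req = FALSE) {
  stopifnot(inherits(morse, "morse_fit"))
  if (inherits(amplitude, "entropy_amplitude")) amplitude <- amplitude$amplitude
  if (inherits(r_cleave, "cleavage_point")) r_cleave <- r_cleave$r_cleave
  if (shrink <= 0 || shrink >= 1) abort("shrink must be in (0, 1)")
  r_end_base <- r_max %||% max(morse$data$distance)
  k <- k_start
  steps <- 0L
  repeat {
    window_end <- max(r_end_base, r_cleave + 10 / k)
    grid <- seq(morse$r_eq, window_end, by = grid_step)
    res <- assemble_gibbs(morse, sigmoid_model(amplitude, r_cleave, k), grid,
                          offset_at_req = offset_at_req)
    res <- find_barrier(res, tol_barrier = tol_barrier)
    res$tuning_steps <- steps
    if (isTRUE(res$no_barrier)) return(res)
    if (post_ts_dip(res) <= tol_min) return(res)
    k <- k * shrink
    steps <- steps + 1L
    if (k < k_floor) {
      abort(sprintf(
        "steepness tuning failed: k_sig fell below the floor %g 1/A without removing the post-TS minimum",
        k_floor))
    }
  }
}

.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(cond) {
    abort(sprintf("[stage %s] %s", stage, conditionMessage(cond)))
  })
}

#' Run the full barrier-estimation pipeline
#'
#' Executes the complete workflow on one dissociation: Morse fit of the scan,
#' min-max normalization and exponential fit of the descriptor, closed-form
#' cleavage distance at `gamma_cleave`, sigmoid steepness tuning, and barrier
#' extraction.  Stage failures are re-raised with the stage name prefixed.
#'
#' @param scan A [dissociation_scan()].
#' @param descriptor A [descriptor_series()] on the same bond and grid;
#'   normalized automatically when raw.
#' @param amplitude Entropy amplitude `-T * dS_diss` in kJ/mol (or an
#'   [entropy_amplitude()] from the RRHO engine).
#' @param gamma_cleave Descriptor slope cutoff (default 0.02, the value that
#'   works well for gas-phase reactions; 0.01 is the better choice in
#'   solution).
#' @param fix_r_eq Optional fixed equilibrium distance for the Morse fit.
#' @param direction `"dissociation"` or `"association"`; both barriers are
#'   always computed, the direction only selects the headline number in
#'   summaries.
#' @param temperature,pressure Thermodynamic state recorded in reports (K,
#'   Pa); `NA` when the amplitude was supplied directly without them.
#' @inheritParams tune_steepness
#' @return A `free_energy_result` carrying every intermediate fit (Morse,
#'   descriptor, cleavage point, sigmoid), the tuned curve and the barriers.
#' @examples
#' case <- synthetic_case(seed = 42)
#' res <- run_pipeline(gen_scan(case), gen_descriptor(case),
#'                     amplitude = case$amplitude)
#' glance(res)
#' @export
run_pipeline <- function(scan, descriptor, amplitude, gamma_cleave = 0.02,
                         fix_r_eq = NULL,
                         direction = c("dissociation", "association"),
                         temperature = NA_real_, pressure = NA_real_,
                         k_start = 10, shrink = 0.9, k_floor = 0.1,
                         grid_step = 1e-3, tol_min = 0.01, tol_barrier = 0.01,
                         offset_at_req = FALSE) {
  direction <- match.arg(direction)
  if (inherits(amplitude, "entropy_amplitude")) {
    if (is.na(temperature)) temperature <- amplitude$temperature
    amplitude <- amplitude$amplitude
  }
  morse <- .with_stage("morse_fit", fit_morse(scan, fix_r_eq = fix_r_eq))
  if (all(is.na(descriptor$normalized_value))) {
    descriptor <- .with_stage("normalize_descriptor", normalize_descriptor(descriptor))
  }
  dfit <- .with_stage("descriptor_fit", fit_descriptor(descriptor))
  cleave <- .with_stage("cleavage_distance", cleavage_distance(dfit, gamma_cleave))
  res <- .with_stage("tune_steepness", tune_steepness(
    morse, amplitude, cleave$r_cleave,
    k_start = k_start, shrink = shrink, k_floor = k_floor,
    grid_step = grid_step, tol_min = tol_min, tol_barrier = tol_barrier,
    r_max = max(scan$distance), offset_at_req = offset_at_req))
  res$descriptor_fit <- dfit
  res$cleavage <- cleave
  res$gamma_cleave <- gamma_cleave
  res$amplitude <- amplitude
  res$temperature <- temperature
  res$pressure <- pressure
  res$direction <- direction
  res
}

#' Sweep the cleavage cutoff
#'
#' Runs [run_pipeline()] once per `gamma_cleave` value and collects the
#' [glance()] rows; the full results are kept in a list column.  Because a
#' larger cutoff places the cleavage point (and hence the entropy onset)
#' closer in, the reported barrier is non-increasing along an increasing
#' cutoff sweep.
#'
#' @param gamma_values Vector of cutoffs, e.g. `c(0.001, 0.002, 0.005, 0.01,
#'   0.02, 0.05, 0.1)`.
#' @inheritParams run_pipeline
#' @param ... Passed on to [run_pipeline()].
#' @return A tibble with one row per cutoff and a `result` list column.
#' @export
gamma_sweep <- function(scan, descriptor, amplitude, gamma_values, ...) {
  results <- purrr::map(gamma_values, function(g) {
    run_pipeline(scan, descriptor, amplitude, gamma_cleave = g, ...)
  })
  out <- purrr::map_dfr(results, glance)
  out$result <- results
  out
}

#' Extract the free-energy curve
#'
#' @param result A `free_energy_result`.
#' @return A tibble with columns `r` (Angstrom) and `delta_g` (kJ/mol).
#' @export
free_energy_curve <- function(result) {
  stopifnot(inherits(result, "free_energy_result"))
  result$curve
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat("<free_energy_result>\n")
  if (isTRUE(x$no_barrier)) {
    cat("  no barrier: the free-energy curve has no interior maximum above its references\n")
  } else {
    cat(sprintf("  transition state at r = %.4f A\n", x$r_ts))
    cat(sprintf("  dissociation barrier: %.4f kJ/mol (vs. complex at r_eq)\n",
                x$barrier_dissociation))
    cat(sprintf("  association barrier:  %.4f kJ/mol (vs. separated fragments)\n",
                x$barrier_association))
  }
  cat(sprintf("  sigmoid: amplitude %.4f kJ/mol, r_cleave %.4f A, k_sig %.4f 1/A\n",
              x$sigmoid$amplitude, x$sigmoid$r_cleave, x$k_sig_final))
  invisible(x)
}

#' @method tidy free_energy_result
#' @export
tidy.free_energy_result <- function(x, ...) {
  tibble(
    term = c("well_depth", "decay", "r_eq", "d0", "k_desc", "gamma_cleave",
             "r_cleave", "amplitude", "k_sig", "r_ts",
             "barrier_dissociation", "barrier_association"),
    estimate = c(x$morse$well_depth, x$morse$decay, x$morse$r_eq,
                 x$descriptor_fit$d0 %||% NA_real_,
                 x$descriptor_fit$k_desc %||% NA_real_,
                 x$gamma_cleave %||% NA_real_,
                 x$sigmoid$r_cleave, x$sigmoid$amplitude, x$k_sig_final,
                 x$r_ts, x$barrier_dissociation, x$barrier_association)
  )
}

#' @method glance free_energy_result
#' @export
glance.free_energy_result <- function(x, ...) {
  tibble(
    well_depth = x$morse$well_depth, decay = x$morse$decay, r_eq = x$morse$r_eq,
    d0 = x$descriptor_fit$d0 %||% NA_real_,
    k_desc = x$descriptor_fit$k_desc %||% NA_real_,
    gamma_cleave = x$gamma_cleave %||% NA_real_,
    r_cleave = x$sigmoid$r_cleave,
    amplitude = x$sigmoid$amplitude,
    k_sig_final = x$k_sig_final,
    r_ts = x$r_ts,
    barrier_dissociation = x$barrier_dissociation,
    barrier_association = x$barrier_association,
    no_barrier = isTRUE(x$no_barrier),
    residual_at_req = x$residual_at_req,
    direction = x$direction %||% NA_character_
  )
}
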