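#' Morse model of the electronic dissociation energy
#'
#' Evaluates `well_depth * (exp(-2*decay*(r - r_eq)) - 2*exp(-decay*(r - r_eq)))`,
#' the Morse form referenced to the separated fragments: the value at `r_eq` is
#' `-well_depth` and the curve approaches 0 from below as `r` grows.
#'
#' @param r Distances in Angstrom.
#' @param well_depth Electronic well depth in kJ/mol (positive).
#' @param decay Morse decay constant in 1/Angstrom (positive).
#' @param r_eq Equilibrium distance in Angstrom.
#' @return Electronic energies in kJ/mol.
#' @export
morse_energy <- function(r, well_depth, decay, r_eq) {
  u <- exp(-decay * (r - r_eq))
  well_depth * (u^2 - 2 * u)
}

#' Fit a Morse potential to a dissociation scan
#'
#' Least-squares fit of the Morse well depth, decay constant and (optionally)
#' equilibrium distance to scan energies that are referenced to 0 at infinite
#' separation.  Starting values are taken from the scan itself: the distance of
#' minimum energy, the negated minimum energy, and a decay constant from the
#' local curvature of the well.
#'
#' @param scan A [dissociation_scan()].
#' @param fix_r_eq Optional equilibrium distance in Angstrom; when given, only
#'   the well depth and decay are fitted and `r_eq` is held at this value (for
#'   workflows that trust the optimized geometry over the fit).
#' @return An object of class `morse_fit` with elements `well_depth`, `decay`,
#'   `r_eq`, `rss` (residual sum of squares, (kJ/mol)^2), `fixed_r_eq` and the
#'   scan used.  Supports [predict()], [tidy()], [glance()] and [autoplot()].
#' @export
fit_morse <- function(scan, fix_r_eq = NULL) {
  stopifnot(inherits(scan, "dissociation_scan"))
  r <- scan$distance
  e <- scan$energy
  i_min <- which.min(e)
  if (e[i_min] >= 0) {
    abort("Morse fit failed: no bound well (minimum energy is not below the separated-fragment reference)")
  }
  if (i_min == length(e)) {
    abort("Morse fit failed: energies decrease monotonically to the end of the scan, inconsistent with a bound well")
  }
  de0 <- -e[i_min]
  req0 <- if (is.null(fix_r_eq)) r[i_min] else fix_r_eq
  # curvature heuristic: quadratic through the well gives k2 = 2 * De * a^2
  idx <- max(1L, i_min - 2L):min(length(r), i_min + 2L)
  k2 <- tryCatch(2 * unname(coef(lm(e[idx] ~ poly(r[idx], 2, raw = TRUE)))[3]),
                 error = function(cond) NA_real_)
  a0 <- if (is.finite(k2) && k2 > 0) sqrt(k2 / (2 * de0)) else 1
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  dat <- list(r = r, e = e)
  fit <- tryCatch({
    if (is.null(fix_r_eq)) {
      minpack.lm::nlsLM(
        e ~ De * (exp(-2 * a * (r - req)) - 2 * exp(-a * (r - req))),
        data = dat, start = list(De = de0, a = a0, req = req0),
        lower = c(De = 1e-12, a = 1e-12, req = -Inf), control = ctrl)
    } else {
      req_fix <- fix_r_eq
      minpack.lm::nlsLM(
        e ~ De * (exp(-2 * a * (r - req_fix)) - 2 * exp(-a * (r - req_fix))),
        data = c(dat, list(req_fix = req_fix)),
        start = list(De = de0, a = a0),
        lower = c(De = 1e-12, a = 1e-12), control = ctrl)
    }
  }, error = function(cond) {
    abort(paste0("Morse fit failed to converge: ", conditionMessage(cond)))
  })
  p <- coef(fit)
  out <- structure(list(
    well_depth = unname(p["De"]),
    decay = unname(p["a"]),
    r_eq = if (is.null(fix_r_eq)) unname(p["req"]) else fix_r_eq,
    rss = sum(residuals(fit)^2),
    fixed_r_eq = !is.null(fix_r_eq),
    data = scan
  ), class = "morse_fit")
  if (!is.finite(out$rss) || out$well_depth <= 0 || out$decay <= 0) {
    abort("Morse fit failed: non-physical parameters (well depth and decay must be positive)")
  }
  out
}

#' @rdname fit_morse
#' @param object A `morse_fit`.
#' @param r Distances in Angstrom at which to evaluate the fitted curve.
#' @param ... Unused.
#' @export
predict.morse_fit <- function(object, r, ...) {
  morse_energy(r, object$well_depth, object$decay, object$r_eq)
}

#' @export
print.morse_fit <- function(x, ...) {
  cat(sprintf(
    "<morse_fit: well depth %.4f kJ/mol, decay %.4f 1/A, r_eq %.4f A%s, rss %.3e>\n",
    x$well_depth, x$decay, x$r_eq, if (x$fixed_r_eq) " (fixed)" else "", x$rss))
  invisible(x)
}

#' @method tidy morse_fit
#' @export
tidy.morse_fit <- function(x, ...) {
  tibble(term = c("well_depth", "decay", "r_eq"),
         estimate = c(x$well_depth, x$decay, x$r_eq),
         unit = c("kJ/mol", "1/Angstrom", "Angstrom"))
}

#' @method glance morse_fit
#' @export
glance.morse_fit <- function(x, ...) {
  tibble(well_depth = x$well_depth, decay = x$decay, r_eq = x$r_eq,
         rss = x$rss, n = nrow(x$data), fixed_r_eq = x$fixed_r_eq)
}
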