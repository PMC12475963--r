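#' Sigmoid model of the entropy onset
#'
#' Constructs the sigmoid `-T dS` model of the entropy recovered along the
#' dissociation coordinate:
#' `amplitude / (1 + exp(-k_sig * (r - r_cleave)))`.
#' Its inflection point sits at the bond-cleavage distance, where by
#' construction exactly half of the total dissociation entropy is recovered;
#' the value tends to 0 well before cleavage and to `amplitude` (the full
#' `-T * (S_A + S_B - S_AB)`) well beyond it.
#'
#' @param amplitude Total entropy amplitude `-T * delta_S_diss` in kJ/mol
#'   (negative for an entropy-gaining dissociation); an
#'   [entropy_amplitude()] row is also accepted.
#' @param r_cleave Cleavage distance in Angstrom (the inflection point); a
#'   [cleavage_distance()] row is also accepted.
#' @param k_sig Sigmoid steepness in 1/Angstrom, positive.
#' @return An object of class `entropy_sigmoid`.
#' @seealso [entropy_sigmoid()], [tune_steepness()]
#' @export
sigmoid_model <- function(amplitude, r_cleave, k_sig) {
  if (inherits(amplitude, "entropy_amplitude")) amplitude <- amplitude$amplitude
  if (inherits(r_cleave, "cleavage_point")) r_cleave <- r_cleave$r_cleave
  if (!is.finite(amplitude) || !is.finite(r_cleave) || !is.finite(k_sig)) {
    abort("amplitude, r_cleave and k_sig must be finite")
  }
  if (k_sig <= 0) abort("k_sig must be positive")
  structure(list(amplitude = amplitude, r_cleave = r_cleave, k_sig = k_sig),
            class = "entropy_sigmoid")
}

#' Evaluate the sigmoid entropy model
#'
#' @param r Distances in Angstrom.
#' @param model An [sigmoid_model()].
#' @return `-T dS` values in kJ/mol; exactly `amplitude / 2` at `r_cleave`.
#' @export
entropy_sigmoid <- function(r, model) {
  stopifnot(inherits(model, "entropy_sigmoid"))
  model$amplitude / (1 + exp(-model$k_sig * (r - model$r_cleave)))
}

#' @export
print.entropy_sigmoid <- function(x, ...) {
  cat(sprintf("<entropy_sigmoid: amplitude %.4f kJ/mol, r_cleave %.4f A, k_sig %.4f 1/A>\n",
              x$amplitude, x$r_cleave, x$k_sig))
  invisible(x)
}

#' @method tidy entropy_sigmoid
#' @export
tidy.entropy_sigmoid <- function(x, ...) {
  tibble(term = c("amplitude", "r_cleave", "k_sig"),
         estimate = c(x$amplitude, x$r_cleave, x$k_sig),
         unit = c("kJ/mol", "Angstrom", "1/Angstrom"))
}
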