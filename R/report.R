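#' Write a machine-readable barrier report
#'
#' Serializes a `free_energy_result` to JSON: every fit parameter (Morse,
#' descriptor, cleavage, sigmoid), the tuned steepness, the curve grid, both
#' barriers (or an explicit no-barrier marker, never a number), the run
#' conditions and the package version.  Numbers are written at full precision
#' so the report round-trips losslessly through [read_report()]; the timestamp
#' is the only field that differs between identical reruns.
#'
#' @param result A `free_energy_result` from [run_pipeline()] (results from
#'   [assemble_gibbs()]/[find_barrier()] work too; absent stages are omitted).
#' @param path Output path for the JSON document.
#' @param seed Optional integer seed to record (for synthetic provenance).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, seed = NULL) {
  stopifnot(inherits(result, "free_energy_result"))
  doc <- list(
    software = list(
      name = "barrierless",
      version = as.character(packageVersion("barrierless")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed
    ),
    conditions = list(
      gamma_cleave = result$gamma_cleave,
      temperature = result$temperature,
      pressure = result$pressure,
      direction = result$direction,
      offset_at_req = result$offset_at_req,
      temperature_assumed = isTRUE(is.na(result$temperature))
    ),
    morse = list(
      well_depth = result$morse$well_depth,
      decay = result$morse$decay,
      r_eq = result$morse$r_eq,
      rss = result$morse$rss,
      fixed_r_eq = result$morse$fixed_r_eq
    ),
    descriptor = if (!is.null(result$descriptor_fit)) list(
      name = result$descriptor_fit$name,
      d0 = result$descriptor_fit$d0,
      k_desc = result$descriptor_fit$k_desc,
      rss = result$descriptor_fit$rss
    ),
    cleavage = if (!is.null(result$cleavage)) list(
      gamma_cleave = result$cleavage$gamma_cleave,
      r_cleave = result$cleavage$r_cleave
    ),
    sigmoid = list(
      amplitude = result$sigmoid$amplitude,
      r_cleave = result$sigmoid$r_cleave,
      k_sig = result$k_sig_final,
      residual_at_req = result$residual_at_req
    ),
    barriers = if (isTRUE(result$no_barrier)) {
      list(no_barrier = TRUE)
    } else {
      list(no_barrier = FALSE,
           r_ts = result$r_ts,
           dissociation = result$barrier_dissociation,
           association = result$barrier_association)
    },
    curve = list(r = result$curve$r, delta_g = result$curve$delta_g)
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    TRUE
  }, error = function(cond) FALSE, warning = function(cond) FALSE)
  if (!ok || !file.exists(path)) abort(sprintf("could not write report to '%s'", path))
  invisible(path)
}

#' Read a barrier report back
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return The report as a nested list, with the curve as numeric vectors.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
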