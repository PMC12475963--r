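#' Construct a dissociation scan
#'
#' A dissociation scan is the tabular result of a relaxed surface scan along a
#' single breaking bond: one electronic energy per bond distance.  Energies are
#' stored in kJ/mol relative to the separated fragments, so the asymptote at
#' infinite separation is exactly 0 and a bound complex has negative energy at
#' its equilibrium distance.
#'
#' @param distances Bond distances in Angstrom.  Sorted internally; duplicates
#'   are an error.
#' @param energies Electronic energies in kJ/mol relative to separated
#'   fragments, one per distance.
#' @param label Free-text label carried through to reports.
#' @return A tibble of class `dissociation_scan` with columns `distance` and
#'   `energy`, sorted by distance.
#' @seealso [read_scan_table()], [fit_morse()]
#' @export
dissociation_scan <- function(distances, energies, label = "scan") {
  if (!is.numeric(distances) || !is.numeric(energies)) {
    abort("distances and energies must be numeric")
  }
  if (length(distances) != length(energies)) {
    abort("distances and energies must have the same length")
  }
  if (length(distances) < 5L) {
    abort(sprintf("a dissociation scan needs at least 5 points, got %d",
                  length(distances)))
  }
  if (!all(is.finite(distances)) || !all(is.finite(energies))) {
    abort("all distances and energies must be finite")
  }
  ord <- order(distances)
  distances <- distances[ord]
  energies <- energies[ord]
  if (any(diff(distances) <= 0)) {
    abort("duplicate distances in scan")
  }
  out <- tibble(distance = distances, energy = energies)
  attr(out, "label") <- as.character(label)[1]
  class(out) <- c("dissociation_scan", class(out))
  out
}

#' Construct a descriptor series
#'
#' Values of a quantum-chemical bond descriptor (e.g. IBSI, Mayer or Laplacian
#' bond order, or an AIM index such as ELF, LIE or LED) sampled along the same
#' scan coordinate as the energies.  Raw values keep the descriptor's native
#' units; `normalized_value` is populated by [normalize_descriptor()] (min-max
#' to \[0, 1\]) or may be supplied directly when the series is already on a
#' dimensionless \[0, 1\] scale.
#'
#' @param distances Bond distances in Angstrom.
#' @param raw_values Descriptor values in native units, one per distance.
#' @param name Descriptor identifier (free text, e.g. `"IBSI"`).
#' @param normalized_values Optional values in \[0, 1\]; usually left `NULL`
#'   and filled by [normalize_descriptor()].
#' @return A tibble of class `descriptor_series` with columns `distance`,
#'   `raw_value` and `normalized_value`.
#' @export
descriptor_series <- function(distances, raw_values, name = "descriptor",
                              normalized_values = NULL) {
  if (length(distances) != length(raw_values)) {
    abort("distances and raw_values must have the same length")
  }
  if (!all(is.finite(distances)) || !all(is.finite(raw_values))) {
    abort("all distances and raw_values must be finite")
  }
  ord <- order(distances)
  distances <- distances[ord]
  raw_values <- raw_values[ord]
  if (any(diff(distances) <= 0)) abort("duplicate distances in descriptor series")
  if (is.null(normalized_values)) {
    normalized_values <- rep(NA_real_, length(distances))
  } else {
    normalized_values <- normalized_values[ord]
    if (any(normalized_values < -1e-12 | normalized_values > 1 + 1e-12)) {
      abort("normalized_values must lie in [0, 1]")
    }
  }
  out <- tibble(distance = distances, raw_value = raw_values,
                normalized_value = normalized_values)
  attr(out, "descriptor_name") <- as.character(name)[1]
  class(out) <- c("descriptor_series", class(out))
  out
}

#' Name of a descriptor series
#' @param series A `descriptor_series`.
#' @return The descriptor identifier as a string.
#' @export
descriptor_name <- function(series) {
  attr(series, "descriptor_name") %||% "descriptor"
}

# Parse a two-column numeric table: comma- or whitespace-separated,
# '#' comments ignored, decimal point only.  Returns a 2-column matrix;
# errors carry the offending (data) row number.
.read_two_column <- function(path, what = "table") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) abort(sprintf("%s '%s' contains no data", what, path))
  rows <- lapply(seq_along(keep), function(i) {
    ln <- gsub(",", " ", lines[keep[i]])
    toks <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      # allow a single header row of labels at the top
      if (i == 1L) return(NULL)
      abort(sprintf("non-numeric value in %s '%s' at data row %d: '%s'",
                    what, path, i, lines[keep[i]]))
    }
    if (length(vals) != 2L) {
      abort(sprintf("expected two columns in %s '%s' at data row %d, found %d",
                    what, path, i, length(vals)))
    }
    vals
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) abort(sprintf("%s '%s' contains no numeric rows", what, path))
  do.call(rbind, rows)
}

#' Read a dissociation scan from a two-column text table
#'
#' Reads `distance energy` rows (comma- or whitespace-separated, `#` comments
#' and an optional header line ignored), converts energies to kJ/mol and
#' re-references them so that the separated-fragment asymptote sits at exactly
#' 0, the convention every downstream fit assumes.
#'
#' @param path Path to the table.
#' @param energy_unit `"kj_per_mol"` or `"hartree"` (converted with
#'   1 Eh = 2625.499639 kJ/mol).
#' @param reference `"separated_fragments"` if the energies in the file are
#'   already relative to the separated fragments; `"raw"` if they are absolute,
#'   in which case `separated_energy` (same unit as the file) must be given and
#'   is subtracted before conversion.
#' @param separated_energy Electronic energy of the separated fragments, in the
#'   file's unit; required when `reference = "raw"`.
#' @param label Label for the scan; defaults to the file name.
#' @return A [dissociation_scan()] sorted by distance.
#' @export
read_scan_table <- function(path,
                            energy_unit = c("kj_per_mol", "hartree"),
                            reference = c("separated_fragments", "raw"),
                            separated_energy = NULL,
                            label = basename(path)) {
  energy_unit <- match.arg(energy_unit)
  reference <- match.arg(reference)
  tab <- .read_two_column(path, "scan table")
  distance <- tab[, 1]
  energy <- tab[, 2]
  if (reference == "raw") {
    if (is.null(separated_energy)) {
      abort("reference = 'raw' requires separated_energy so the asymptote can be set to 0")
    }
    energy <- energy - separated_energy
  }
  if (energy_unit == "hartree") energy <- energy * .const$hartree_kj
  dissociation_scan(distance, energy, label = label)
}

#' Write a dissociation scan to a two-column text table
#'
#' Full-precision inverse of [read_scan_table()]: reading the written file with
#' default settings reproduces the scan exactly.
#'
#' @param scan A [dissociation_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(scan, path) {
  stopifnot(inherits(scan, "dissociation_scan"))
  hdr <- sprintf("# dissociation scan '%s': distance [A], energy [kJ/mol, 0 at infinite separation]",
                 attr(scan, "label") %||% "scan")
  body <- sprintf("%.17g %.17g", scan$distance, scan$energy)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a descriptor series from a two-column text table
#'
#' @param path Path to a `distance value` table (same dialect as
#'   [read_scan_table()]).
#' @param name Descriptor identifier.
#' @return A [descriptor_series()] with raw values only.
#' @export
read_descriptor_table <- function(path, name = basename(path)) {
  tab <- .read_two_column(path, "descriptor table")
  descriptor_series(tab[, 1], tab[, 2], name = name)
}

#' Write a descriptor series to a two-column text table
#'
#' Writes the raw values at full precision.
#'
#' @param series A [descriptor_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(series, path) {
  stopifnot(inherits(series, "descriptor_series"))
  hdr <- sprintf("# descriptor series '%s': distance [A], raw value", descriptor_name(series))
  writeLines(c(hdr, sprintf("%.17g %.17g", series$distance, series$raw_value)), path)
  invisible(path)
}

#' Read an XYZ geometry
#'
#' Standard XYZ: first line the atom count, second a comment, then one
#' `symbol x y z` line per atom with coordinates in Angstrom.
#'
#' @param path Path to the XYZ file.
#' @return A list with `element_symbols` (character) and `coordinates`
#'   (numeric matrix, one row per atom, columns x/y/z in Angstrom).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) abort(sprintf("empty XYZ file: %s", path))
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) abort(sprintf("invalid atom count line in %s", path))
  atom_lines <- lines[-(1:2)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  if (length(atom_lines) < n) {
    abort(sprintf("XYZ '%s' declares %d atoms but has %d coordinate lines",
                  path, n, length(atom_lines)))
  }
  atom_lines <- atom_lines[seq_len(n)]
  parsed <- strsplit(trimws(atom_lines), "[[:space:]]+")
  symbols <- character(n)
  coords <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(n)) {
    toks <- parsed[[i]]
    if (length(toks) < 4L) abort(sprintf("malformed atom line %d in %s", i, path))
    symbols[i] <- toks[1]
    xyz <- suppressWarnings(as.numeric(toks[2:4]))
    if (anyNA(xyz)) abort(sprintf("non-numeric coordinate at atom %d in %s", i, path))
    coords[i, ] <- xyz
  }
  if (!all(symbols %in% names(.atomic_masses))) {
    bad <- unique(symbols[!symbols %in% names(.atomic_masses)])
    abort(sprintf("unknown element symbol(s) in %s: %s", path,
                  paste(bad, collapse = ", ")))
  }
  list(element_symbols = symbols, coordinates = coords)
}

#' Read a list of harmonic frequencies
#'
#' Accepts either a plain-text list of wavenumbers (one or more per line, `#`
#' comments ignored) or a JSON array (`.json` extension).
#'
#' @param path Path to the frequency list.
#' @return Numeric vector of wavenumbers in cm^-1.
#' @export
read_frequencies <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    v <- jsonlite::fromJSON(path)
    if (!is.numeric(v)) abort(sprintf("JSON frequency file %s is not a numeric array", path))
    return(as.numeric(v))
  }
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  toks <- unlist(strsplit(trimws(lines[nzchar(trimws(lines))]), "[[:space:]]+"))
  v <- suppressWarnings(as.numeric(toks))
  if (anyNA(v)) abort(sprintf("non-numeric entry in frequency list %s", path))
  v
}

#' @export
print.dissociation_scan <- function(x, ...) {
  cat(sprintf("<dissociation_scan '%s': %d points, %.3f-%.3f A, min energy %.3f kJ/mol>\n",
              attr(x, "label") %||% "scan", nrow(x), min(x$distance),
              max(x$distance), min(x$energy)))
  NextMethod()
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat(sprintf("<descriptor_series '%s': %d points, %s>\n",
              descriptor_name(x), nrow(x),
              if (all(is.na(x$normalized_value))) "raw only" else "normalized"))
  NextMethod()
}
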