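test_that("scan tables round-trip at full precision and honour units and references", {
  case <- default_case(seed = 11, noise_energy = 0.05)
  scan <- gen_scan(case)
  path <- withr::local_tempfile(fileext = ".dat")

  write_scan_table(scan, path)
  back <- read_scan_table(path)
  expect_identical(back$distance, scan$distance)
  expect_identical(back$energy, scan$energy)

  # the standard scan protocol: 82 rows from 1.95 to 6.00 A in 0.05 A steps
  expect_equal(nrow(scan), 82L)
  expect_equal(scan$distance[1], 1.95)
  expect_equal(scan$distance[82], 6.00)

  # hartree input converts with 1 Eh = 2625.499639 kJ/mol
  eh <- scan$energy / 2625.499639
  writeLines(sprintf("%.17g %.17g", scan$distance, eh), path)
  back_eh <- read_scan_table(path, energy_unit = "hartree")
  expect_equal(back_eh$energy, scan$energy, tolerance = 1e-12)

  # raw absolute energies are re-referenced so the asymptote is 0
  writeLines(sprintf("%.17g %.17g", scan$distance, scan$energy - 152.3), path)
  back_raw <- read_scan_table(path, reference = "raw", separated_energy = -152.3)
  expect_equal(back_raw$energy, scan$energy, tolerance = 1e-12)
  expect_error(read_scan_table(path, reference = "raw"), "separated_energy")
})

test_that("unit conversion Eh -> kJ/mol and back is the identity", {
  x <- c(-0.0123456789, 0, 1.5e-3)
  expect_equal((x * 2625.499639) / 2625.499639, x, tolerance = 1e-10)
})

test_that("shuffled rows are sorted with values kept paired", {
  path <- withr::local_tempfile(fileext = ".dat")
  r <- c(3.0, 2.0, 2.5, 4.0, 3.5, 2.2)
  e <- c(-5, -20, -11, -2, -3.5, -16)
  writeLines(c("# shuffled", sprintf("%g, %g", r, e)), path)  # comma dialect
  scan <- read_scan_table(path)
  ord <- order(r)
  expect_equal(scan$distance, r[ord])
  expect_equal(scan$energy, e[ord])
})

test_that("malformed scan tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("2.0 -20", "2.5 -11", "3.0 -5", "3.5 -3"), path)
  expect_error(read_scan_table(path), "at least 5")
  writeLines(c("2.0 -20", "2.5 -11", "2.5 -10", "3.0 -5", "3.5 -3"), path)
  expect_error(read_scan_table(path), "duplicate")
  writeLines(c("2.0 -20", "2.5 -11", "3.0 oops", "3.5 -3", "4.0 -1"), path)
  expect_error(read_scan_table(path), "row 3")
  expect_error(read_scan_table(file.path(tempdir(), "no-such-file.dat")),
               "not found")
  expect_error(dissociation_scan(c(1, 2, 3, 4, 5), c(0, NA, 0, 0, 0)), "finite")
})

test_that("XYZ geometries parse and validate atom counts and symbols", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(
    "6", "water dimer",
    "O  -1.551007  -0.114520   0.000000",
    "H  -1.934259   0.762503   0.000000",
    "H  -0.599677   0.040712   0.000000",
    "O   1.350625   0.111469   0.000000",
    "H   1.680398  -0.373741  -0.758561",
    "H   1.680398  -0.373741   0.758561"), path)
  geom <- read_xyz(path)
  expect_length(geom$element_symbols, 6)
  expect_identical(dim(geom$coordinates), c(6L, 3L))
  expect_identical(geom$element_symbols[c(1, 4)], c("O", "O"))

  writeLines(c("1", "argon atom", "Ar 0.0 0.0 0.0"), path)
  expect_identical(read_xyz(path)$element_symbols, "Ar")

  writeLines(c("5", "short", "H 0 0 0", "H 0 0 1", "H 0 1 0", "H 1 0 0"), path)
  expect_error(read_xyz(path), "declares 5 atoms but has 4")

  writeLines(c("1", "bogus", "Xx 0 0 0"), path)
  expect_error(read_xyz(path), "unknown element")
})

test_that("frequency lists read from plain text and JSON", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# freqs in cm-1", "120.5", "860.1 1200.0", "3650.2"), path)
  expect_equal(read_frequencies(path), c(120.5, 860.1, 1200.0, 3650.2))
  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines('[55.2, 101.0, 1600.4]', jpath)
  expect_equal(read_frequencies(jpath), c(55.2, 101.0, 1600.4))
})

test_that("descriptor tables round-trip and keep their name", {
  case <- default_case(seed = 4, noise_descriptor = 0.01)
  d <- gen_descriptor(case)
  path <- withr::local_tempfile(fileext = ".dat")
  write_descriptor_table(d, path)
  back <- read_descriptor_table(path, name = "IBSI")
  expect_identical(back$distance, d$distance)
  expect_identical(back$raw_value, d$raw_value)
  expect_identical(descriptor_name(back), "IBSI")
})
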