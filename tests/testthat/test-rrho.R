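R_gas <- 8.31446261815324

test_that("translational entropy matches the Sackur-Tetrode oracle and its analytic dependences", {
  s_ar <- translational_entropy(0.039948, 298.15, 101325)
  expect_equal(s_ar, st_oracle(0.039948, 298.15, 101325), tolerance = 1e-10)
  expect_lt(abs(s_ar - st_oracle(0.039948, 298.15, 101325)), 0.01)
  # monotone in T
  expect_gt(translational_entropy(0.039948, 596.30, 101325), s_ar)
  # doubling P lowers S by exactly R ln 2
  expect_equal(s_ar - translational_entropy(0.039948, 298.15, 2 * 101325),
               R_gas * log(2), tolerance = 1e-12)
  expect_error(translational_entropy(-1, 298.15, 101325), "positive")
})

test_that("rotational entropy handles atoms, linear rotors and symmetry numbers", {
  expect_identical(rotational_entropy("Ar", matrix(0, 1, 3)), 0)

  # rigid diatomic vs. the linear-rotor closed form evaluated independently
  sym <- c("H", "Cl")
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1.2746))
  s_pkg <- rotational_entropy(sym, xyz, 1, 298.15)
  mu <- prod(orc_masses[sym]) / sum(orc_masses[sym]) * orc$amu
  I_si <- mu * (1.2746e-10)^2
  theta <- (orc$h / (2 * pi))^2 / (2 * I_si * orc$kB)
  s_closed <- orc$R * (1 + log(298.15 / theta))
  expect_equal(s_pkg, s_closed, tolerance = 1e-10)
  expect_lt(abs(s_pkg - s_closed), 0.01)

  # sigma doubling lowers S by exactly R ln 2
  xyz4 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  sym4 <- c("C", "H", "H", "H")
  expect_equal(rotational_entropy(sym4, xyz4, 1) - rotational_entropy(sym4, xyz4, 2),
               R_gas * log(2), tolerance = 1e-12)

  expect_error(rotational_entropy(c("H", "H"), matrix(0, 2, 3)), "coincident")
})

test_that("vibrational entropy applies the low-frequency raising convention", {
  expect_identical(vibrational_entropy(numeric(0)), 0)
  # a 50 cm-1 mode raised to 100 equals a genuine 100 cm-1 mode
  expect_identical(vibrational_entropy(50, 298.15, raising_cutoff = 100),
                   vibrational_entropy(100, 298.15, raising_cutoff = 100))
  # single mode against the partition-function oracle
  expect_equal(vibrational_entropy(200, 298.15, raising_cutoff = 0),
               vib_oracle(200, 298.15), tolerance = 1e-6)
  # cutoff 0 reproduces the plain harmonic result
  f <- c(35, 80, 450, 1700)
  expect_equal(vibrational_entropy(f, 298.15, raising_cutoff = 0),
               vib_oracle(f, 298.15), tolerance = 1e-6)
  # raising is idempotent: shifting already-shifted modes changes nothing
  expect_identical(vibrational_entropy(pmax(f, 100), 298.15, 100),
                   vibrational_entropy(f, 298.15, 100))
  # raising only ever increases low modes, giving lower entropy than unshifted
  expect_lt(vibrational_entropy(f, 298.15, 100),
            vibrational_entropy(f, 298.15, 0))
  expect_error(vibrational_entropy(c(-120, 500)), "imaginary")
  expect_warning(v <- vibrational_entropy(c(-120, 500), discard_imaginary = TRUE),
                 "discarding")
  expect_equal(v, vibrational_entropy(500))
})

test_that("electronic entropy is R log(multiplicity)", {
  expect_identical(electronic_entropy(1), 0)
  expect_equal(electronic_entropy(2), R_gas * log(2), tolerance = 1e-12)
  expect_equal(electronic_entropy(2), 5.763, tolerance = 1e-3)
  expect_equal(electronic_entropy(3) / electronic_entropy(2),
               log(3) / log(2), tolerance = 1e-12)
  expect_error(electronic_entropy(0), ">= 1")
})

test_that("every entropy component matches the independent oracle on 20 random species", {
  for (i in 1:20) {
    sp <- random_species(i)
    s_tr <- translational_entropy(molar_mass(sp$sym), sp$temp, sp$pres)
    expect_equal(s_tr, st_oracle(sum(orc_masses[sp$sym]) * 1e-3, sp$temp, sp$pres),
                 tolerance = 1e-6)
    s_rot <- rotational_entropy(sp$sym, sp$xyz, sp$sigma, sp$temp)
    expect_equal(s_rot, rot_oracle(sp$sym, sp$xyz, sp$sigma, sp$temp),
                 tolerance = 1e-6)
    if (length(sp$freqs)) {
      expect_equal(vibrational_entropy(sp$freqs, sp$temp, raising_cutoff = 0),
                   vib_oracle(sp$freqs, sp$temp), tolerance = 1e-6)
    }
    expect_equal(electronic_entropy(sp$mult), orc$R * log(sp$mult),
                 tolerance = 1e-12)
    # full decomposition is additive
    st <- species_entropy(sp$sym, sp$xyz, sp$freqs, sp$mult, sp$sigma,
                          sp$temp, sp$pres)
    expect_equal(st$s_total, st$s_trans + st$s_rot + st$s_vib + st$s_elec,
                 tolerance = 1e-9)
    expect_equal(st$minus_T_S, -sp$temp * st$s_total / 1000, tolerance = 1e-9)
    expect_gt(st$s_trans, 0)
    expect_gte(st$s_vib, 0)
  }
})

test_that("species_entropy validates mode counts", {
  sym <- c("O", "H", "H")
  xyz <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
  expect_error(species_entropy(sym, xyz, rep(1000, 4)), "at most 3")
  expect_silent(species_entropy(sym, xyz, c(1600, 3650, 3750)))
})

test_that("entropy amplitude bookkeeping and consistency checks", {
  sym <- c("O", "H", "H")
  xyz <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
  w <- species_entropy(sym, xyz, c(1600, 3650, 3750), symmetry_number = 2,
                       label = "water")
  dimer_sym <- c(sym, sym)
  dimer_xyz <- rbind(xyz, sweep(xyz, 2, c(2.9, 0, 0), "+"))
  ab <- species_entropy(dimer_sym, dimer_xyz,
                        c(150, 180, 200, 350, 600, 640,
                          1600, 1620, 3650, 3660, 3750, 3760),
                        label = "dimer")
  amp <- entropy_amplitude(ab, w, w)
  # fragments jointly carry more entropy than the complex: amplitude < 0
  expect_equal(amp$delta_s_diss, 2 * w$s_total - ab$s_total, tolerance = 1e-12)
  expect_lt(amp$amplitude, 0)
  expect_equal(amp$amplitude, -298.15 * amp$delta_s_diss / 1000, tolerance = 1e-12)
  # tens of kJ/mol, the canonical scale of a two-fragment dissociation
  expect_gt(abs(amp$amplitude), 10)
  expect_lt(abs(amp$amplitude), 100)

  # identical species as complex and both fragments: amplitude = -T * S(one species)
  amp_id <- entropy_amplitude(w, w, w)
  expect_equal(amp_id$amplitude, -298.15 * w$s_total / 1000, tolerance = 1e-12)

  # zero entropy difference gives exactly 0
  half <- w
  half$s_total <- ab$s_total / 2
  class(half) <- class(w)
  expect_equal(entropy_amplitude(ab, half, half)$amplitude, 0)

  w_cold <- species_entropy(sym, xyz, c(1600, 3650, 3750), temperature = 200)
  expect_error(entropy_amplitude(ab, w, w_cold), "same temperature")
})
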