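# Shared synthetic-case builders.
#
# default_case(): the water-dimer-like reference conditions (hydrogen-bond
# well, IBSI-like slow descriptor decay, 1.95-6 A scan in 0.05 A steps);
# used for qualitative behaviour (sweeps, robustness).
#
# validation_case(): randomized covalent-like conditions with a fast-decaying
# descriptor over a 6 A span, for which the composed pipeline-vs-oracle
# problem is numerically self-consistent at sub-1e-3 kJ/mol.

default_case <- function(seed = 1L, ...) {
  synthetic_case(seed = seed, ...)
}

validation_case <- function(seed) {
  withr::with_seed(seed + 1000L, {
    req <- runif(1, 1.9, 2.1)
    synthetic_case(
      well_depth = runif(1, 15, 60),
      decay = runif(1, 1.5, 2.5),
      r_eq = req,
      k_desc = runif(1, 2.2, 3.2),
      amplitude = runif(1, -45, -25),
      r_start = req, r_end = req + 6, step = 0.05,
      seed = seed
    )
  })
}

random_species <- function(seed) {
  withr::with_seed(seed + 2000L, {
    n <- sample(2:7, 1)
    sym <- sample(c("H", "C", "N", "O", "Cl", "S"), n, replace = TRUE)
    xyz <- matrix(rnorm(3 * n, sd = 1.2), n, 3)
    nf <- sample(0:max(3 * n - 6, 1), 1)
    nf <- max(0, min(nf, 3 * n - 6))
    list(
      sym = sym, xyz = xyz,
      freqs = sort(runif(nf, 120, 3500)),
      sigma = sample(c(1, 2, 3, 12), 1),
      mult = sample(1:4, 1),
      temp = runif(1, 150, 1000),
      pres = runif(1, 5e4, 2e5)
    )
  })
}
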