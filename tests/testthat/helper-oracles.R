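# Independent oracles, coded separately from the package internals:
# statistical-mechanics entropies via the thermal de Broglie wavelength and
# numeric temperature derivatives of ln q, brute-force grid searches for the
# nonlinear fits, bisection for the cleavage root, and dense-grid curve
# maximization.  These deliberately avoid the package's formulations.

orc <- list(
  R = 8.31446261815324, kB = 1.380649e-23, h = 6.62607015e-34,
  NAv = 6.02214076e23, ccm = 2.99792458e10, amu = 1.66053906660e-27
)

orc_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                F = 18.998403162, Cl = 35.45, Br = 79.904, S = 32.06,
                P = 30.973761998, Ar = 39.95)

# Sackur-Tetrode through the thermal de Broglie wavelength
st_oracle <- function(molar_mass_kg, temp, pres) {
  m <- molar_mass_kg / orc$NAv
  lambda <- orc$h / sqrt(2 * pi * m * orc$kB * temp)
  orc$R * (log(orc$kB * temp / (pres * lambda^3)) + 2.5)
}

# S = R ln q + R T dlnq/dT with Richardson-extrapolated central differences
S_from_lnq <- function(lnq, temp, h_step = 0.5) {
  d1 <- (lnq(temp + h_step) - lnq(temp - h_step)) / (2 * h_step)
  d2 <- (lnq(temp + h_step / 2) - lnq(temp - h_step / 2)) / h_step
  orc$R * lnq(temp) + orc$R * temp * (4 * d2 - d1) / 3
}

inertia_oracle <- function(sym, xyz) {
  m <- orc_masses[sym]
  com <- colSums(xyz * m) / sum(m)
  d <- sweep(xyz, 2, com)
  imat <- diag(sum(m * rowSums(d^2)), 3) - t(d) %*% (d * m)
  sort(eigen(imat, symmetric = TRUE, only.values = TRUE)$values)
}

rot_oracle <- function(sym, xyz, sigma, temp) {
  I_amu <- inertia_oracle(sym, xyz)
  I_si <- I_amu * orc$amu * 1e-20
  hbar <- orc$h / (2 * pi)
  if (I_amu[1] < 1e-3) {
    theta <- hbar^2 / (2 * mean(I_si[2:3]) * orc$kB)
    S_from_lnq(function(t) log(t / (sigma * theta)), temp)
  } else {
    theta <- hbar^2 / (2 * I_si * orc$kB)
    S_from_lnq(function(t) {
      log(sqrt(pi) / sigma) + 1.5 * log(t) - 0.5 * log(prod(theta))
    }, temp)
  }
}

vib_oracle <- function(freqs, temp) {
  if (length(freqs) == 0L) return(0)
  theta <- orc$h * orc$ccm * freqs / orc$kB
  S_from_lnq(function(t) sum(-log1p(-exp(-theta / t))), temp)
}

# brute-force coarse-to-fine grid search minimizing the Morse SSE
morse_grid_oracle <- function(r, e, n_grid = 15, n_refine = 7) {
  sse <- function(de, a, req) {
    u <- exp(-a * (r - req))
    sum((e - de * (u^2 - 2 * u))^2)
  }
  de_rng <- c(0.5, 1.5) * -min(e)
  a_rng <- c(0.3, 4)
  req_rng <- range(r)
  best <- NULL
  for (it in seq_len(n_refine)) {
    g <- expand.grid(de = seq(de_rng[1], de_rng[2], length.out = n_grid),
                     a = seq(a_rng[1], a_rng[2], length.out = n_grid),
                     req = seq(req_rng[1], req_rng[2], length.out = n_grid))
    vals <- vapply(seq_len(nrow(g)),
                   function(i) sse(g$de[i], g$a[i], g$req[i]), numeric(1))
    best <- g[which.min(vals), ]
    shrink <- 0.35
    de_rng <- best$de + c(-1, 1) * shrink * diff(de_rng) / 2
    a_rng <- pmax(best$a + c(-1, 1) * shrink * diff(a_rng) / 2, 1e-6)
    req_rng <- best$req + c(-1, 1) * shrink * diff(req_rng) / 2
  }
  list(well_depth = best$de, decay = best$a, r_eq = best$req,
       tol = c(well_depth = diff(de_rng), decay = diff(a_rng),
               r_eq = diff(req_rng)))
}

# 2-D grid search for the exponential descriptor fit
descriptor_grid_oracle <- function(r, v, n_grid = 41, n_refine = 7) {
  sse <- function(d0, k) sum((v - d0 * exp(-k * r))^2)
  d0_rng <- c(0.2, 5) * max(v) * exp(min(r))
  k_rng <- c(0.2, 5)
  best <- NULL
  for (it in seq_len(n_refine)) {
    g <- expand.grid(d0 = seq(d0_rng[1], d0_rng[2], length.out = n_grid),
                     k = seq(k_rng[1], k_rng[2], length.out = n_grid))
    vals <- vapply(seq_len(nrow(g)), function(i) sse(g$d0[i], g$k[i]), numeric(1))
    best <- g[which.min(vals), ]
    shrink <- 0.3
    d0_rng <- pmax(best$d0 + c(-1, 1) * shrink * diff(d0_rng) / 2, 1e-9)
    k_rng <- pmax(best$k + c(-1, 1) * shrink * diff(k_rng) / 2, 1e-9)
  }
  list(d0 = best$d0, k_desc = best$k,
       tol = c(d0 = diff(d0_rng), k_desc = diff(k_rng)))
}

# bisection root of |d/dr d0 e^{-kr}| - gamma on [lo, hi]
bisect_cleavage <- function(d0, k, gamma, lo = 0.1, hi = 60) {
  f <- function(r) k * d0 * exp(-k * r) - gamma
  stopifnot(f(lo) > 0, f(hi) < 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-13) break
  }
  (lo + hi) / 2
}

# dense-grid maximum of an arbitrary curve function
grid_max_oracle <- function(f, lo, hi, step = 1e-4) {
  r <- seq(lo, hi, by = step)
  g <- f(r)
  i <- which.max(g)
  list(r = r[i], g = g[i], interior = i > 1L && i < length(g))
}

# independent post-TS dip scan on an analytic curve
dip_oracle <- function(f, r_ts, hi, asymptote, step = 1e-3) {
  g <- c(f(seq(r_ts, hi, by = step)), asymptote)
  max(g - cummin(g))
}
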