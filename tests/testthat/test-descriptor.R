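test_that("min-max normalization is the expected affine map", {
  s <- descriptor_series(c(2, 2.5, 3), c(4, 2, 3))
  n <- normalize_descriptor(s)
  # raw (4, 2, 3) sorted by distance -> normalized (1, 0, 0.5)
  expect_equal(n$normalized_value, c(1, 0, 0.5))
  expect_equal(min(n$normalized_value), 0)
  expect_equal(max(n$normalized_value), 1)

  # an already-[0,1] series is unchanged
  s01 <- descriptor_series(c(2, 2.5, 3, 3.5), c(1, 0.6, 0.2, 0))
  expect_equal(normalize_descriptor(s01)$normalized_value, s01$raw_value)

  # order is preserved for a monotone decreasing series
  r <- seq(2, 6, by = 0.5)
  sm <- normalize_descriptor(descriptor_series(r, exp(-r) + 0.05))
  expect_true(all(diff(sm$normalized_value) < 0))

  expect_error(normalize_descriptor(descriptor_series(c(2, 3, 4), rep(0.7, 3))),
               "degenerate")
})

test_that("exact exponential descriptor values are recovered to 1e-6", {
  r <- seq(1.95, 6, by = 0.05)
  v <- 1.0 * exp(-1.5 * r)
  fit <- fit_descriptor(descriptor_series(r, v, normalized_values = v))
  expect_equal(fit$d0, 1.0, tolerance = 1e-6)
  expect_equal(fit$k_desc, 1.5, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-16)
})

test_that("noisy descriptor fits agree with the 2-D grid-search oracle", {
  case <- default_case(seed = 31, noise_descriptor = 0.02)
  d <- normalize_descriptor(gen_descriptor(case))
  fit <- fit_descriptor(d)
  g <- descriptor_grid_oracle(d$distance, d$normalized_value)
  expect_lt(abs(fit$d0 - g$d0), max(g$tol["d0"], 1e-3))
  expect_lt(abs(fit$k_desc - g$k_desc), max(g$tol["k_desc"], 1e-3))
  sse <- function(d0, k) sum((d$normalized_value - d0 * exp(-k * d$distance))^2)
  expect_lte(fit$rss, sse(g$d0, g$k_desc) + 1e-9)
})

test_that("the fitted exponential is locally optimal against +/-10% decay perturbations", {
  case <- default_case(seed = 5, noise_descriptor = 0.01)
  d <- normalize_descriptor(gen_descriptor(case))
  fit <- fit_descriptor(d)
  sse_at_k <- function(k) {
    # conditionally optimal amplitude for a fixed decay (linear least squares)
    basis <- exp(-k * d$distance)
    d0 <- sum(d$normalized_value * basis) / sum(basis^2)
    sum((d$normalized_value - d0 * basis)^2)
  }
  expect_lt(fit$rss, sse_at_k(fit$k_desc * 0.9))
  expect_lt(fit$rss, sse_at_k(fit$k_desc * 1.1))
})

test_that("non-decaying descriptors are rejected as unsuitable", {
  r <- seq(2, 6, by = 0.5)
  v <- (r - 1.5) / 5
  expect_error(fit_descriptor(descriptor_series(r, v, normalized_values = v / max(v))),
               "unsuitable")
})

test_that("the cleavage distance matches its closed form and the bisection oracle", {
  # hand case: d0 = 1, k = 1, gamma = 0.05 -> r_cleave = log(20)
  r <- seq(0.5, 8, by = 0.1)
  v <- exp(-r)
  fit <- fit_descriptor(descriptor_series(r, v, normalized_values = v))
  cp <- cleavage_distance(fit, 0.05)
  expect_equal(cp$r_cleave, log(20), tolerance = 1e-9)
  # defining condition holds with equality
  slope <- fit$k_desc * fit$d0 * exp(-fit$k_desc * cp$r_cleave)
  expect_equal(slope, 0.05, tolerance = 1e-9)

  # closed form vs. bisection on random fits
  for (seed in 1:5) {
    case <- validation_case(seed)
    dfit <- fit_descriptor(normalize_descriptor(gen_descriptor(case)))
    for (gamma in c(0.01, 0.02, 0.1)) {
      rc <- cleavage_distance(dfit, gamma)$r_cleave
      expect_equal(rc, bisect_cleavage(dfit$d0, dfit$k_desc, gamma),
                   tolerance = 1e-9)
    }
    # monotone: a larger cutoff breaks the bond earlier
    expect_gt(cleavage_distance(dfit, 0.01)$r_cleave,
              cleavage_distance(dfit, 0.10)$r_cleave)
  }
})

test_that("a cutoff above the initial slope means the bond is already broken", {
  r <- seq(2, 6, by = 0.1)
  v <- exp(-1.2 * r) / exp(-1.2 * 2)
  fit <- fit_descriptor(descriptor_series(r, v, normalized_values = v))
  # slope magnitude at the scan start is k * 1 = 1.2
  expect_error(cleavage_distance(fit, 1.3), "already broken at equilibrium")
  expect_error(cleavage_distance(fit, -0.1), "positive")
})
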