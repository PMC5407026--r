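test_that("repiling with identity noise is the identity on histograms", {
  q <- c(0, 0, 0, 3, 3, 7, 12)
  h <- repile_histogram(q, noise_identity())
  expect_equal(h$support, c(3, 7, 12))
  expect_equal(h$weights, c(2, 1, 1))
  expect_equal(h$n_zero, 3)
})

test_that("repiling inverts amplification and inflates by inverse detection", {
  # alpha = 2, beta = 1, no dropout: Q in {0,2,4} x (5,3,2) -> Y {1,2}, w (3,2)
  q <- c(rep(0, 5), rep(2, 3), rep(4, 2))
  h <- repile_histogram(q, noise_params(2, 1, Inf, 0))
  expect_equal(h$support, c(1, 2))
  expect_equal(h$weights, c(3, 2))
  expect_equal(h$n_zero, 5)
  # kappa = tau = 0: every weight doubles (expit(0) = 0.5)
  h2 <- repile_histogram(q, noise_params(2, 1, 0, 0))
  expect_equal(h2$weights, c(6, 4))
})

test_that("repiled weight always totals the number of cells", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    q <- rpois(n, sample(c(0.5, 2, 20), 1))
    noise <- noise_params(runif(1, 0.5, 3), runif(1, 0.6, 1.2),
                          runif(1, -3, 3), runif(1, 0, 1.5))
    h <- repile_histogram(q, noise)
    expect_equal(sum(h$weights) + h$n_zero, n, tolerance = 1e-9)
    expect_true(all(h$weights >= 0) && h$n_zero >= 0)
  }
})

test_that("factorial moments match analytic values on large samples", {
  h0 <- repile_histogram(rep(0, 10), noise_identity())
  expect_equal(unname(factorial_moments(h0)), c(0, 0, 0))
  kp <- kinetic_params(0.2, 0.2, 50)
  n <- 1e5
  sim <- simulate_true_expression(kp, kp, phi = rep(1, n), seed = 52)
  y <- sim$y_a
  h <- repile_histogram(y, noise_identity())
  m <- factorial_moments(h)
  fm <- forward_moments(0.2, 0.2, 50)
  se <- function(v) sd(v) / sqrt(n)
  expect_lt(abs(m[["m1"]] - fm$m1), 3 * se(y))
  expect_lt(abs(m[["m2"]] - fm$m2), 3 * se(y * (y - 1)))
  expect_lt(abs(m[["m3"]] - fm$m3), 3 * se(y * (y - 1) * (y - 2)))
  # doubling phi halves m1 for fixed Y
  m2x <- factorial_moments(h, phi = rep(2, n))
  expect_equal(m2x[["m1"]], m[["m1"]] / 2)
})

test_that("moment inversion is the exact inverse of the forward equations", {
  m <- forward_moments(0.2, 0.2, 50)
  est <- invert_moments(m$m1, m$m2, m$m3)
  expect_true(est$estimable)
  expect_equal(est$k_on, 0.2, tolerance = 1e-8)
  expect_equal(est$k_off, 0.2, tolerance = 1e-8)
  expect_equal(est$s, 50, tolerance = 1e-8)
  set.seed(53)
  for (i in 1:100) {
    k_on <- runif(1, 0.05, 5); k_off <- runif(1, 0.05, 5); s <- runif(1, 5, 500)
    m <- forward_moments(k_on, k_off, s)
    est <- invert_moments(m$m1, m$m2, m$m3)
    expect_true(est$estimable)
    expect_lt(max(abs(c(est$k_on, est$k_off, est$s) - c(k_on, k_off, s)) /
                    c(k_on, k_off, s)), 1e-6)
  }
})

test_that("the constitutive (pure Poisson) limit is flagged non-estimable", {
  lam <- 25
  est <- invert_moments(lam, lam^2, lam^3) # exact Poisson factorial moments
  expect_false(est$estimable)
})

test_that("identical alleles yield identical estimates and CIs", {
  set.seed(54)
  q <- rpois(150, 8) * rbinom(150, 1, 0.6)
  out <- estimate_allele_kinetics(q, q, noise_identity(), n_boot = 50)
  expect_equal(out$burst_frequency[1], out$burst_frequency[2])
  expect_equal(out$se_burst_size[1], out$se_burst_size[2])
  expect_equal(out$ci_lo_burst_frequency[1], out$ci_lo_burst_frequency[2])
})

test_that("a constitutive-like gene is flagged unstable", {
  set.seed(55)
  kp <- kinetic_params(5, 0.05, 60)
  sim <- simulate_true_expression(kp, kp, phi = rep(1, 120))
  out <- estimate_allele_kinetics(sim$y_a, sim$y_b, noise_identity(),
                                  n_boot = 60)
  expect_true(all(out$unstable))
})

test_that("burst size is more stable than s or k_off when k_on << k_off", {
  set.seed(56)
  k_on <- 0.3; k_off <- 3; s <- 150
  kp <- kinetic_params(k_on, k_off, s)
  rel_err <- t(replicate(150, {
    sim <- simulate_true_expression(kp, kp, phi = rep(1, 200))
    e <- estimate_kinetics(sim$y_a, noise_identity())
    if (!e$estimable) return(c(NA, NA, NA))
    c(size = abs(e$burst_size - s / k_off) / (s / k_off),
      s = abs(e$s - s) / s,
      k_off = abs(e$k_off - k_off) / k_off)
  }))
  med <- apply(rel_err, 2, median, na.rm = TRUE)
  expect_lt(med[["size"]], med[["s"]])
  expect_lt(med[["size"]], med[["k_off"]])
})

test_that("noise and cell-size adjustment reduce estimation error", {
  set.seed(57)
  np <- noise_default()
  kp <- kinetic_params(0.2, 0.2, 100)
  err <- t(replicate(60, {
    phi <- simulate_cell_sizes(300, 0.2)
    sim <- simulate_true_expression(kp, kp, phi = phi)
    q <- apply_technical_noise(sim$y_a, np)$q
    full <- estimate_kinetics(q, np, phi = phi)
    raw <- estimate_kinetics(q, noise_identity(), phi = phi)
    c(full = if (full$estimable) abs(full$burst_frequency - 0.2) / 0.2 else Inf,
      raw = if (raw$estimable) abs(raw$burst_frequency - 0.2) / 0.2 else Inf)
  }))
  expect_lt(median(err[, "full"]), median(err[, "raw"]))
})
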