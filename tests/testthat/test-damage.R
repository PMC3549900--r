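test_that("derived constants satisfy both anchor identities", {
  dc <- derive_damage_constants(0.38, 0.0174, 0.0015)
  # independent direct evaluation of the defining formulas
  gamma_oracle <- log(1 / (1 - 0.38)) / log(0.0015 / 0.0174)
  expect_equal(dc$gamma, gamma_oracle, tolerance = 1e-15)
  expect_equal(dc$kappa, 0.0015^(-gamma_oracle), tolerance = 1e-15)
  expect_equal(1 - dc$kappa * 0.0015^dc$gamma, 0, tolerance = 1e-12)
  expect_equal(1 - dc$kappa * 0.0174^dc$gamma, 0.38, tolerance = 1e-12)
  # published approximate values (printed to 5 decimals)
  expect_equal(dc$gamma, -0.19504, tolerance = 5e-5)
  expect_equal(dc$kappa, 0.28133, tolerance = 5e-5)
  # identities hold across other parameter sets too
  for (prm in list(c(0.2, 0.01, 0.001), c(0.6, 0.03, 0.004))) {
    d <- derive_damage_constants(prm[1], prm[2], prm[3])
    expect_equal(1 - d$kappa * prm[3]^d$gamma, 0, tolerance = 1e-12)
    expect_equal(1 - d$kappa * prm[2]^d$gamma, prm[1], tolerance = 1e-12)
  }
  expect_error(derive_damage_constants(1.2, 0.0174, 0.0015),
    class = "osteofem_input_error")
  expect_error(derive_damage_constants(0.38, 0.001, 0.0015),
    class = "osteofem_input_error")
})

test_that("equivalent strain is symmetric, non-negative and matches an eigen oracle", {
  expect_equal(equivalent_strain(0.002, 0, 0), 0.002)
  expect_equal(equivalent_strain(-0.003, 0, 0), 0.003)
  expect_equal(equivalent_strain(0.001, 0.001, 0.001), 0)
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))
  e <- c(0.004, -0.001, 0.0003)
  vals <- vapply(perms, function(p)
    equivalent_strain(e[p[1]], e[p[2]], e[p[3]]), numeric(1))
  expect_true(all(abs(vals - vals[1]) < 1e-15))
  # full random tensors: Voigt route == formula applied to eigenvalues
  set.seed(42)
  for (k in 1:20) {
    s <- matrix(rnorm(9, sd = 2e-3), 3)
    s <- (s + t(s)) / 2
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    voigt <- c(s[1, 1], s[2, 2], s[3, 3], 2 * s[1, 2], 2 * s[2, 3], 2 * s[1, 3])
    expect_equal(
      osteofem:::equivalent_strain_voigt(matrix(voigt, 1)),
      equivalent_strain(ev[1], ev[2], ev[3]),
      tolerance = 1e-12
    )
  }
})

test_that("damage law honours the threshold and its anchors", {
  p <- damage_params()
  expect_equal(damage_from_strain(0.0015, p), 0)
  expect_equal(damage_from_strain(0.0005, p), 0)
  expect_equal(damage_from_strain(0.0174, p), 0.38, tolerance = 1e-12)
  # continuity at the threshold and strict monotonicity above it
  expect_lt(damage_from_strain(0.0015 + 1e-10, p), 1e-6)
  grid <- seq(0.0016, 0.05, length.out = 100)
  expect_true(all(diff(damage_from_strain(grid, p)) > 0))
  expect_error(damage_from_strain(-1e-6, p), class = "osteofem_input_error")
  # supercritical values are allowed but flagged
  d_big <- damage_from_strain(0.05, p)
  expect_gt(d_big, p$d_cri)
  expect_true(is_supercritical(d_big, p))
  expect_false(is_supercritical(0.1, p))
})

test_that("cycle counts are additive and match quadrature of the growth law", {
  p <- damage_params() # beta = 5
  pp <- paris_params()
  expect_equal(cycles_between(0.2, 0.2, p, pp), 0)
  n12 <- cycles_between(0.1, 0.2, p, pp)
  n23 <- cycles_between(0.2, 0.38, p, pp)
  n13 <- cycles_between(0.1, 0.38, p, pp)
  expect_equal(n12 + n23, n13, tolerance = 1e-10)
  # independent oracle: adaptive quadrature of dN = da / (alpha (ds g sqrt(a))^beta)
  quad <- stats::integrate(function(a) a^(-p$beta / 2), lower = 0.1,
    upper = 0.38, rel.tol = 1e-12)$value
  expect_equal(n13, quad, tolerance = 1e-8)
  # with non-unit Paris constants the prefactor scales the count
  pp2 <- paris_params(alpha = 2, delta_sigma = 3, gamma_k = 1.5, omega = 0.8)
  expected <- ((0.8 * 0.1)^(-1.5) - (0.8 * 0.38)^(-1.5)) /
    (2 * 3^5 * 1.5^5 * 1.5)
  expect_equal(cycles_between(0.1, 0.38, p, pp2), expected, tolerance = 1e-12)
  expect_error(cycles_between(0, 0.2, p, pp), class = "osteofem_input_error")
  expect_error(cycles_between(0.3, 0.2, p, pp), class = "osteofem_input_error")
})

test_that("normalized probability is anchored, monotone and Paris-independent", {
  p <- damage_params()
  expect_equal(fracture_probability(0, p), 0)
  expect_equal(fracture_probability(p$d_cri, p), 1, tolerance = 1e-12)
  expect_equal(fracture_probability(p$d_cri / 2, p), 0.5^1.5, tolerance = 1e-12)
  grid <- seq(0, p$d_cri, length.out = 50)
  expect_true(all(diff(fracture_probability(grid, p)) > 0))
  expect_equal(fracture_probability(2 * p$d_cri, p), 1) # clamped
  expect_error(fracture_probability(-0.1, p), class = "osteofem_input_error")
  # P through the strain chain is monotone non-decreasing in eps_c
  eps <- seq(0, 0.03, length.out = 200)
  chain <- fracture_probability(damage_from_strain(eps, p), p)
  expect_true(all(diff(chain) >= -1e-15))
  # the cycle-count normalization is independent of the Paris constants
  d <- seq(0.05, 0.37, length.out = 7)
  norm_with <- function(paris) {
    1 - cycles_between(d, p$d_cri, p, paris) /
      cycles_between(min(d), p$d_cri, p, paris)
  }
  expect_equal(norm_with(paris_params()),
    norm_with(paris_params(alpha = 7, delta_sigma = 0.2, gamma_k = 3,
      omega = 0.5)),
    tolerance = 1e-12)
})
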