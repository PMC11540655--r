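# Near-incompressible Neo-Hookean constitutive behaviour.

# spectral-form oracle: W from the principal stretches (eigenvalues of F'F)
energy_oracle <- function(F, m) {
  lam2 <- eigen(t(F) %*% F, symmetric = TRUE, only.values = TRUE)$values
  J <- sqrt(prod(lam2))
  0.5 * m$mu * (J^(-2 / 3) * sum(lam2) - 3) + 0.5 * m$kappa * (J - 1)^2
}

test_that("material constructors validate physical ranges", {
  m <- material(E = 25, nu = 0.49, rho = 1000)
  expect_equal(m$mu, 25 / (2 * 1.49))
  expect_equal(m$kappa, 25 / (3 * 0.02))
  expect_error(material(E = -1, nu = 0.4), "E > 0")
  expect_error(material(mu = 10, kappa = 50), "kappa/mu")
  expect_error(material(E = 10, nu = 0.49, rho = -2), "density")
  # kappa/mu >= 10 enforced (near-incompressibility)
  expect_gte(m$kappa / m$mu, 10)
})

test_that("strain energy vanishes exactly on rotations and matches the spectral oracle", {
  m <- material(E = 25, nu = 0.49)
  expect_identical(strain_energy(diag(3), m), 0)
  set.seed(5)
  for (i in 1:10) {
    R <- random_rotation()
    expect_lt(abs(strain_energy(R, m)), 1e-12)
  }
  for (i in 1:50) {
    F <- random_F(c(0.5, 2))
    expect_equal(strain_energy(F, m), energy_oracle(F, m),
                 tolerance = 1e-12)
    expect_gte(strain_energy(F, m), 0)
  }
  expect_error(strain_energy(diag(c(1, 1, -1)), m), "inverted")
})

test_that("objectivity: W(RF) = W(F) for random rotations", {
  m <- material(E = 25, nu = 0.49)
  set.seed(6)
  for (i in 1:20) {
    F <- random_F()
    R <- random_rotation()
    if (det(R) < 0) R[, 1] <- -R[, 1]
    expect_equal(strain_energy(R %*% F, m), strain_energy(F, m),
                 tolerance = 1e-10)
  }
})

test_that("first Piola-Kirchhoff stress is the derivative of the energy", {
  m <- material(E = 25, nu = 0.49)
  expect_equal(pk1_stress(diag(3), m), matrix(0, 3, 3))
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    F <- random_F(c(0.3, 2.5))
    P <- pk1_stress(F, m)
    d <- 1e-6
    Pfd <- matrix(0, 3, 3)
    for (r in 1:3) for (c in 1:3) {
      Fp <- F; Fp[r, c] <- Fp[r, c] + d
      Fm <- F; Fm[r, c] <- Fm[r, c] - d
      Pfd[r, c] <- (strain_energy(Fp, m) - strain_energy(Fm, m)) / (2 * d)
    }
    worst <- max(worst, max(abs(P - Pfd)) / max(abs(P)))
  }
  expect_lt(worst, 1e-6)
})

test_that("uniaxial nominal stress matches the 1-D root-finding solution", {
  m <- material(E = 25, nu = 0.49)
  p_diag <- function(l1, l3) {
    FF <- diag(c(l1, l1, l3))
    diag(pk1_stress(FF, m))
  }
  for (l3 in c(0.85, 1.25)) {
    l1 <- uniroot(function(l) {
      # independent scalar evaluation of the lateral stress component
      J <- l * l * l3
      I1 <- 2 * l^2 + l3^2
      m$mu * J^(-2 / 3) * (l - I1 / (3 * l)) + m$kappa * (J - 1) * J / l
    }, c(0.7, 1.5), tol = 1e-13)$root
    p <- p_diag(l1, l3)
    expect_lt(abs(p[1]), 1e-9)
    expect_lt(abs(p[2]), 1e-9)
    # stress from the package's full tensor path equals the scalar formula
    J <- l1 * l1 * l3
    I1 <- 2 * l1^2 + l3^2
    p3 <- m$mu * J^(-2 / 3) * (l3 - I1 / (3 * l3)) + m$kappa * (J - 1) * J / l3
    expect_equal(p[3], p3, tolerance = 1e-12)
  }
})

test_that("energy grows monotonically along uniaxial stretch", {
  m <- material(E = 25, nu = 0.49)
  lam <- seq(1, 1.8, by = 0.05)
  W <- vapply(lam, function(l) strain_energy(diag(c(1, 1, l)), m), 0)
  expect_true(all(diff(W) > 0))
})

test_that("effective material applies the stiffening scale multiplicatively", {
  fx <- fix_phantom()
  field <- material_field(fx$domain)
  # scale 1 everywhere before any needle event
  expect_true(all(field$scale == 1))
  m0 <- effective_material(field, 1)
  expect_equal(m0$mu, field$mu0[1])
  field$scale[1] <- 30
  m30 <- effective_material(field, 1)
  expect_equal(m30$mu, 30 * field$mu0[1])
  expect_equal(m30$kappa, 30 * field$kappa0[1])
  expect_equal(m30$rho, field$rho[1])  # density never scaled
  # anchor-then-catheter composition caps at the maximum, never the product
  cfg <- insertion_config()
  plan <- generate_needle_plan(fx$domain)
  anchors <- plan[plan$type == "anchor", ]
  f1 <- apply_anchor_stiffening(material_field(fx$domain), anchors,
                                fx$domain, cfg)
  f2 <- apply_catheter_stiffening(f1, plan[plan$type == "catheter", ][1, ],
                                  cfg, fx$domain)
  expect_equal(max(f2$scale), 30)
  f3 <- apply_catheter_stiffening(f2, plan[plan$type == "catheter", ][1, ],
                                  cfg, fx$domain)
  expect_identical(f2$scale, f3$scale)  # idempotent
})
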