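test_that("biaxial kinematics build the expected invariants", {
  st <- deformation_from_stretches(1, 1)
  expect_equal(st$F, diag(3))
  expect_equal(st$I1, 3)
  expect_equal(st$I4, 1)

  st <- deformation_from_stretches(1.2, 1.0)
  expect_equal(st$I4, 1.44)
  expect_equal(st$J, 1)

  st <- deformation_from_stretches(1.1, 1.05)
  F <- diag(c(1.1, 1.05, 1 / (1.1 * 1.05)))
  expect_equal(st$I1, sum(diag(t(F) %*% F)), tolerance = 1e-14)
  expect_equal(st$I1, 1.1^2 + 1.05^2 + 1 / (1.1 * 1.05)^2, tolerance = 1e-14)

  expect_error(deformation_from_stretches(0, 1), "positive")
  expect_error(deformation_from_stretches(1, -2), "positive")
})

test_that("strain energy vanishes at the identity for all laws", {
  id <- deformation_from_stretches(1, 1)
  for (law in c("W1", "W2", "W3")) {
    expect_equal(strain_energy(porcine_leaflet_params(law), id), 0)
  }
  # random non-negative parameters too
  set.seed(41)
  for (i in 1:20) {
    p <- material_params("W1", C10 = runif(1, 0, 20), C01 = runif(1, 0, 20),
                         k1 = runif(1, 0, 50), k2 = runif(1, 0, 80))
    expect_equal(strain_energy(p, id), 0)
  }
})

test_that("W3 energy matches an independent term-by-term evaluation", {
  p <- porcine_leaflet_params("W3")
  st <- deformation_from_stretches(1.05, 1.05)
  # each term coded separately from the definition
  C1 <- 19.59; a <- 12.94; b <- 77.79
  I1 <- 1.05^2 + 1.05^2 + 1 / (1.05 * 1.05)^2
  I4 <- 1.05^2
  w_expected <- C1 * (I1 - 3) + a / (2 * b) * (exp(b * (I4 - 1)^2) - 1)
  expect_equal(strain_energy(p, st), w_expected, tolerance = 1e-14)
})

test_that("W2 reduces to its isotropic part when I4 = 1", {
  p <- porcine_leaflet_params("W2")
  # fiber along z is unstretched when lambda3 = 1, i.e. lambda2 = 1/lambda1
  st <- deformation_state(diag(c(1.15, 1 / 1.15, 1)), f0 = c(0, 0, 1))
  expect_equal(st$I4, 1, tolerance = 1e-14)
  i1 <- st$I1 - 3
  expect_gt(i1, 0)
  w_iso <- 1.18 * i1 + 55.04 * (exp(8.08 * i1^2) - 1)
  expect_equal(strain_energy(p, st), w_iso, tolerance = 1e-12)
})

test_that("mismatched law/parameters are rejected", {
  expect_error(material_params("W1", C1 = 1, a = 1, b = 1), "requires")
  expect_error(material_params("W3", C1 = 1, a = -2, b = 1), ">= 0")
})

test_that("Cauchy stress is zero at identity with the reference pressure", {
  id <- deformation_from_stretches(1, 1)
  ref_p <- list(W1 = 2 * 1.21 * 7.99, W2 = 2 * 1.18, W3 = 2 * 19.59)
  for (law in c("W1", "W2", "W3")) {
    s <- cauchy_stress(porcine_leaflet_params(law), id, p = ref_p[[law]])
    expect_equal(s$sigma, matrix(0, 3, 3), tolerance = 1e-13)
  }
})

test_that("stress matches the finite-difference hyperelasticity oracle", {
  set.seed(42)
  for (law in c("W1", "W2", "W3")) {
    p <- porcine_leaflet_params(law)
    for (i in 1:30) {
      st <- random_incompressible_state()
      s_pkg <- cauchy_stress(p, st, p = 0)$sigma
      s_fd <- fd_cauchy_oracle(p, st)
      expect_equal(s_pkg, s_fd, tolerance = 1e-5)
      expect_equal(s_pkg, t(s_pkg), tolerance = 1e-12)  # symmetry
    }
  }
})

test_that("strain energy is frame indifferent", {
  set.seed(43)
  p <- porcine_leaflet_params("W1")
  st <- deformation_from_stretches(1.08, 1.03)
  w0 <- strain_energy(p, st)
  for (i in 1:50) {
    A <- matrix(rnorm(9), 3, 3)
    Q <- qr.Q(qr(A))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    wq <- strain_energy(p, deformation_state(Q %*% st$F, st$f0))
    expect_equal(wq, w0, tolerance = 1e-10)
  }
})

test_that("Piola conversion round-trips and matches closed forms", {
  id <- deformation_from_stretches(1, 1)
  sig <- matrix(c(3, 1, 0, 1, 2, 0, 0, 0, 1), 3, 3)
  expect_equal(piola_from_cauchy(id, sig), sig)

  st <- deformation_state(diag(c(2, 1, 0.5)))
  expect_equal(piola_from_cauchy(st, diag(3)), diag(c(0.5, 1, 2)))

  set.seed(44)
  for (i in 1:20) {
    st <- random_incompressible_state()
    A <- matrix(rnorm(9), 3, 3)
    sig <- crossprod(A) + diag(3)  # SPD
    P <- piola_from_cauchy(st, sig)
    expect_equal(cauchy_from_piola(st, P), sig, tolerance = 1e-12)
  }
  expect_error(piola_from_cauchy(
    structure(list(F = diag(c(1, 1, 0)), J = 0), class = "deformation_state"),
    diag(3)), "det")
})

test_that("plane-stress biaxial response matches the bisection oracle", {
  for (law in c("W1", "W2", "W3")) {
    p <- porcine_leaflet_params(law)
    m <- planar_biaxial_stress(p, 1.1, 1.05)
    ora <- bisect_plane_stress(p, 1.1, 1.05)
    expect_equal(m$sigma11, ora$sigma11, tolerance = 1e-8)
    expect_equal(m$sigma22, ora$sigma22, tolerance = 1e-8)
    expect_lt(abs(ora$sigma33), 1e-10)
    # explicit tensor reconstruction satisfies plane stress
    st <- deformation_from_stretches(1.1, 1.05)
    co <- valvemech:::stress_coefficients(p, st$I1, st$I4)
    full <- cauchy_stress(p, st, p = co$iso / (1.1 * 1.05)^2)
    expect_lt(abs(full$sigma[3, 3]), 1e-10)
    expect_equal(full$sigma[1, 1], m$sigma11, tolerance = 1e-12)
    expect_equal(full$sigma[2, 2], m$sigma22, tolerance = 1e-12)
  }
})

test_that("biaxial response is zero at rest and anisotropic under load", {
  set.seed(45)
  for (law in c("W1", "W2", "W3")) {
    p <- porcine_leaflet_params(law)
    m <- planar_biaxial_stress(p, 1, 1)
    expect_equal(m$sigma11, 0)
    expect_equal(m$sigma22, 0)
    # fiber term only adds to sigma11 on the equal-stretch path
    lam <- seq(1.01, 1.3, length.out = 15)
    mm <- planar_biaxial_stress(p, lam, lam)
    expect_true(all(mm$sigma11 >= mm$sigma22))
    # strictly increasing sigma11 on the equibiaxial path
    lam2 <- seq(1, 1.3, length.out = 40)
    s11 <- planar_biaxial_stress(p, lam2, lam2)$sigma11
    expect_true(all(diff(s11) > 0))
  }
  # anisotropy ordering holds for random non-negative W1 parameters too
  for (i in 1:10) {
    p <- material_params("W1", C10 = runif(1, 0, 5), C01 = runif(1, 0, 5),
                         k1 = runif(1, 0, 20), k2 = runif(1, 0, 20))
    lam <- seq(1.01, 1.25, length.out = 8)
    mm <- planar_biaxial_stress(p, lam, lam)
    expect_true(all(mm$sigma11 >= mm$sigma22))
  }
})

test_that("fiber strain equals (I4 - 1)/2", {
  expect_equal(fiber_strain(deformation_from_stretches(1, 1)), 0)
  expect_equal(fiber_strain(deformation_from_stretches(1.2, 1.07)), 0.22)
  set.seed(46)
  for (i in 1:20) {
    st <- random_incompressible_state()
    expect_equal(fiber_strain(st), (st$I4 - 1) / 2, tolerance = 1e-12)
  }
})

test_that("fiber stress is the normal stress along the deformed fiber", {
  st <- deformation_from_stretches(1.15, 1.02)
  # isotropic stress: any direction sees s
  expect_equal(fiber_stress(st, 7.5 * diag(3)), 7.5)
  # uniaxial stress perpendicular to the (deformed) fiber sees zero
  sig_perp <- matrix(0, 3, 3); sig_perp[2, 2] <- 100
  expect_equal(fiber_stress(st, sig_perp), 0)
  # direct quadratic form with explicit normalization
  p <- porcine_leaflet_params("W1")
  sig <- cauchy_stress(p, st, p = 3)$sigma
  fh <- st$f / sqrt(sum(st$f^2))
  expect_equal(fiber_stress(st, sig), drop(fh %*% sig %*% fh),
               tolerance = 1e-12)
})

test_that("material parameters survive a JSON round trip", {
  p <- porcine_leaflet_params("W2")
  tmp <- withr::local_tempfile(fileext = ".json")
  material_to_json(p, tmp)
  q <- material_from_json(tmp)
  expect_equal(q$law, "W2")
  expect_equal(q$params, p$params)
})
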