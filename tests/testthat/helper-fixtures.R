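# mesh fixtures and numerical oracles shared across test files

# flat unit-square grid in the z = 0 plane, right-triangulated,
# FD2 labels on the x = 0 / x = 1 edges, FD1 corners at (0,0) and (1,1)
grid_mesh <- function(n) {
  n <- as.integer(n)
  xs <- seq(0, 1, length.out = n)
  pts <- as.matrix(expand.grid(x = xs, y = xs))
  V <- cbind(pts, z = 0)
  idx <- function(i, j) (j - 1L) * n + i
  tr <- matrix(0L, 2L * (n - 1L)^2, 3L)
  k <- 0L
  for (j in seq_len(n - 1L)) {
    for (i in seq_len(n - 1L)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      cc <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      tr[k + 1L, ] <- c(a, b, cc)
      tr[k + 2L, ] <- c(a, cc, d)
      k <- k + 2L
    }
  }
  leaflet_mesh(V, tr, list(
    tau1 = which(V[, 1] == 0), tau2 = which(V[, 1] == 1),
    n1 = idx(1L, 1L), n2 = idx(n, n)))
}

# flat annular sector r in [1, 2], theta in [0, pi/3]. Default FD2 labels
# on the two radial edges (analytic harmonic u = theta / (pi/3)); with
# arc_dirichlet = TRUE the labels sit on the inner/outer arcs instead
# (analytic harmonic u = log(r)/log(2), not reproduced exactly by the
# structured mesh, so it exposes the genuine O(h^2) convergence)
annular_mesh <- function(n, arc_dirichlet = FALSE) {
  n <- as.integer(n)
  thetas <- seq(0, pi / 3, length.out = n)
  rs <- seq(1, 2, length.out = n)
  idx <- function(i, j) (j - 1L) * n + i   # i over theta, j over r
  V <- matrix(0, n * n, 3)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    V[idx(i, j), ] <- c(rs[j] * cos(thetas[i]), rs[j] * sin(thetas[i]), 0)
  }
  tr <- matrix(0L, 2L * (n - 1L)^2, 3L)
  k <- 0L
  for (j in seq_len(n - 1L)) for (i in seq_len(n - 1L)) {
    a <- idx(i, j); b <- idx(i + 1L, j)
    cc <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    tr[k + 1L, ] <- c(a, b, cc)
    tr[k + 2L, ] <- c(a, cc, d)
    k <- k + 2L
  }
  if (arc_dirichlet) {
    m <- leaflet_mesh(V, tr, list(
      tau1 = vapply(seq_len(n), function(i) idx(i, 1L), integer(1)),
      tau2 = vapply(seq_len(n), function(i) idx(i, n), integer(1))))
    attr(m, "u_exact") <- log(rep(rs, each = n)) / log(2)
  } else {
    m <- leaflet_mesh(V, tr, list(
      tau1 = vapply(seq_len(n), function(j) idx(1L, j), integer(1)),
      tau2 = vapply(seq_len(n), function(j) idx(n, j), integer(1))))
    attr(m, "u_exact") <- rep(thetas, times = n) / (pi / 3)
  }
  m
}

# quarter-cylinder patch of radius R, axial extent 1; FD2 labels on the
# two axial edges; the exact potential is theta / (pi/2)
cylinder_mesh <- function(n, R = 1.3) {
  n <- as.integer(n)
  thetas <- seq(0, pi / 2, length.out = n)
  zs <- seq(0, 1, length.out = n)
  idx <- function(i, j) (j - 1L) * n + i
  V <- matrix(0, n * n, 3)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    V[idx(i, j), ] <- c(R * cos(thetas[i]), R * sin(thetas[i]), zs[j])
  }
  tr <- matrix(0L, 2L * (n - 1L)^2, 3L)
  k <- 0L
  for (j in seq_len(n - 1L)) for (i in seq_len(n - 1L)) {
    a <- idx(i, j); b <- idx(i + 1L, j)
    cc <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    tr[k + 1L, ] <- c(a, b, cc)
    tr[k + 2L, ] <- c(a, cc, d)
    k <- k + 2L
  }
  leaflet_mesh(V, tr, list(
    tau1 = vapply(seq_len(n), function(j) idx(1L, j), integer(1)),
    tau2 = vapply(seq_len(n), function(j) idx(n, j), integer(1))))
}

# random volume-preserving deformation gradient (J = 1) and random unit
# fiber; moderate distortion so all laws stay in double range
random_incompressible_state <- function() {
  repeat {
    F <- diag(3) + matrix(stats::runif(9, -0.15, 0.15), 3, 3)
    d <- det(F)
    if (d > 0.3) break
  }
  F <- F / d^(1 / 3)
  f0 <- stats::rnorm(3)
  deformation_state(F, f0 / sqrt(sum(f0^2)))
}

# independent hyperelasticity oracle: sigma + pI should equal
# J^-1 (dW/dF) F^T with dW/dF from central finite differences
fd_cauchy_oracle <- function(params, state, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- state$F; Fp[i, j] <- Fp[i, j] + h
    Fm <- state$F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (strain_energy(params, deformation_state(Fp, state$f0)) -
                strain_energy(params, deformation_state(Fm, state$f0))) /
               (2 * h)
  }
  (P %*% t(state$F)) / state$J
}

# independent plane-stress oracle: bisection on the pressure p such that
# the 33-component of the full Cauchy tensor vanishes
bisect_plane_stress <- function(params, l1, l2, tol = 1e-13) {
  st <- deformation_from_stretches(l1, l2)
  s33 <- function(p) cauchy_stress(params, st, p)$sigma[3, 3]
  lo <- -1e6; hi <- 1e6
  stopifnot(s33(lo) > 0, s33(hi) < 0)   # s33 is decreasing in p
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (s33(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  p <- (lo + hi) / 2
  sig <- cauchy_stress(params, st, p)$sigma
  list(p = p, sigma11 = sig[1, 1], sigma22 = sig[2, 2], sigma33 = sig[3, 3])
}

# rectangular-pulse cycle: +100 mL/s for 0.3 s systole, -20 mL/s for
# 0.1 s closing, -1 mL/s for 0.4 s leakage; phase switches are resolved
# with a negligible transition interval so trapezoids stay exact
rect_pulse_waveform <- function(eps = 1e-9) {
  t <- c(0, 0.3, 0.3 + eps, 0.4, 0.4 + eps, 0.8)
  Q <- c(100, 100, -20, -20, -1, -1)
  waveform(t, Q, events = list(t_bs = 0, t_es = 0.3, t_close = 0.4 + eps,
                               t_cycle_end = 0.8))
}
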