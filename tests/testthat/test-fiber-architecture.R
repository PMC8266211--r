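test_that("cotangent Laplacian matches hand assembly on one triangle", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  m <- leaflet_mesh(V, rbind(c(1, 2, 3)))
  L <- as.matrix(cotan_laplacian(m))
  off <- -1 / tan(pi / 3) / 2          # -cot(60 deg)/2
  Lh <- matrix(off, 3, 3)
  diag(Lh) <- -2 * off
  expect_equal(L, Lh, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Laplacian rows sum to zero and interior matches 5-point stencil", {
  m <- grid_mesh(7)
  L <- cotan_laplacian(m)
  expect_lt(max(abs(Matrix::rowSums(L))), 1e-12)
  expect_equal(as.matrix(L), t(as.matrix(L)), tolerance = 1e-14)
  # right-triangulated unit grid: diagonal edges carry zero cotangent
  # weight, so an interior row is the classic (4, -1, -1, -1, -1) stencil
  idx <- function(i, j) (j - 1) * 7 + i
  v <- idx(4, 4)
  row <- as.numeric(L[v, ])
  expect_equal(row[v], 4)
  nbrs <- c(idx(3, 4), idx(5, 4), idx(4, 3), idx(4, 5))
  expect_equal(row[nbrs], rep(-1, 4))
  expect_equal(sum(row != 0), 5)

  # leaflet fixture too
  lm <- generate_leaflet_mesh(6)
  expect_lt(max(abs(Matrix::rowSums(cotan_laplacian(lm)))), 1e-10)
})

test_that("degenerate triangles are reported by index", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  m <- leaflet_mesh(V, rbind(c(1, 2, 4), c(1, 2, 3)))
  expect_error(cotan_laplacian(m), "triangle index 2")
})

test_that("FD2 on a flat square is the linear harmonic u = x", {
  m <- grid_mesh(9)
  sol <- solve_fiber_potential(m, "FD2")
  expect_lt(max(abs(sol$u - m$vertices[, 1])), 1e-10)
  expect_lt(sol$residual, 1e-10)
  f <- fiber_directions(m, sol)
  expect_lt(max(abs(sweep(f, 2, c(1, 0, 0)))), 1e-10)
})

test_that("FD1 point constraints give a harmonic field in [0, 1]", {
  # two-triangle square with corners constrained
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  m <- leaflet_mesh(V, rbind(c(1, 2, 3), c(1, 3, 4)),
                    labels = list(n1 = 1, n2 = 3))
  sol <- solve_fiber_potential(m, "FD1")
  expect_equal(sol$u[1], 1)
  expect_equal(sol$u[3], 0)
  expect_true(all(sol$u >= -1e-12 & sol$u <= 1 + 1e-12))

  # swapping the corners reflects the solution: u -> 1 - u
  m2 <- leaflet_mesh(V, rbind(c(1, 2, 3), c(1, 3, 4)),
                     labels = list(n1 = 3, n2 = 1))
  sol2 <- solve_fiber_potential(m2, "FD1")
  expect_equal(sol2$u, 1 - sol$u, tolerance = 1e-12)

  expect_error(solve_fiber_potential(
    leaflet_mesh(V, rbind(c(1, 2, 3), c(1, 3, 4))), "FD1"), "n1")
})

test_that("FD1 refinement converges toward a fine-mesh reference", {
  sols <- lapply(c(9, 17, 33), function(n) {
    m <- grid_mesh(n)
    solve_fiber_potential(m, "FD1")$u
  })
  ref_n <- 65
  ref <- solve_fiber_potential(grid_mesh(ref_n), "FD1")$u
  # grids nest: compare at the coarsest grid's vertices
  l2_at_coarse <- function(u, n) {
    stride <- (ref_n - 1) / (n - 1)
    idx_c <- function(i, j) (j - 1) * n + i
    idx_r <- function(i, j) (j - 1) * ref_n + i
    err2 <- 0
    for (j in seq_len(n)) for (i in seq_len(n)) {
      rr <- idx_r((i - 1) * stride + 1, (j - 1) * stride + 1)
      err2 <- err2 + (u[idx_c(i, j)] - ref[rr])^2
    }
    sqrt(err2 / n^2)
  }
  errs <- mapply(l2_at_coarse, sols, c(9, 17, 33))
  expect_true(all(diff(errs) < 0))
})

test_that("FD2 on an annular sector matches the angular harmonic", {
  # the structured sector mesh reproduces u = theta/delta-theta exactly;
  # fibers are azimuthal
  m <- annular_mesh(17)
  sol <- solve_fiber_potential(m, "FD2")
  expect_lt(max(abs(sol$u - attr(m, "u_exact"))), 1e-10)
  f <- fiber_directions(m, sol)
  cent <- (m$vertices[m$triangles[, 1], ] + m$vertices[m$triangles[, 2], ] +
           m$vertices[m$triangles[, 3], ]) / 3
  theta <- atan2(cent[, 2], cent[, 1])
  tangential <- f[, 1] * (-sin(theta)) + f[, 2] * cos(theta)
  expect_true(all(abs(tangential) > 0.999))
})

test_that("harmonic solves converge at second order on the sector", {
  # radial log-harmonic (Dirichlet on the arcs) is not exactly
  # representable, so it measures the genuine discretization order
  errs <- vapply(c(9, 17, 33), function(n) {
    m <- annular_mesh(n, arc_dirichlet = TRUE)
    sol <- solve_fiber_potential(m, "FD2")
    sqrt(mean((sol$u - attr(m, "u_exact"))^2))
  }, numeric(1))
  rates <- errs[-length(errs)] / errs[-1]
  expect_true(all(rates > 2.5 & rates < 6.5))   # ~4 per uniform refinement
})

test_that("the discrete maximum principle holds on all fixtures", {
  fixtures <- list(grid_mesh(9), annular_mesh(9), cylinder_mesh(9),
                   generate_leaflet_mesh(8))
  for (m in fixtures) {
    for (arch in c("FD2", if (!is.null(m$labels$n1)) "FD1")) {
      sol <- solve_fiber_potential(m, arch)
      expect_gte(min(sol$u), -1e-12)
      expect_lte(max(sol$u), 1 + 1e-12)
      expect_equal(range(sol$u), c(0, 1), tolerance = 1e-12)
    }
  }
  # extremes attained only at constrained vertices on a Delaunay grid
  m <- grid_mesh(9)
  sol <- solve_fiber_potential(m, "FD2")
  constrained <- c(m$labels$tau1, m$labels$tau2)
  inner <- setdiff(seq_along(sol$u), constrained)
  expect_true(all(sol$u[inner] > 0 & sol$u[inner] < 1))
})

test_that("fiber directions are unit, tangent, and circumferential on a cylinder", {
  m <- cylinder_mesh(17)
  sol <- solve_fiber_potential(m, "FD2")
  f <- fiber_directions(m, sol)
  expect_lt(max(abs(sqrt(rowSums(f^2)) - 1)), 1e-12)
  nrm <- valvemech:::triangle_normals(m)
  expect_lt(max(abs(rowSums(f * nrm))), 1e-10)
  # azimuthal: no axial component, positive sense around the axis
  expect_lt(max(abs(f[, 3])), 1e-6)
  cent <- (m$vertices[m$triangles[, 1], ] + m$vertices[m$triangles[, 2], ] +
           m$vertices[m$triangles[, 3], ]) / 3
  theta <- atan2(cent[, 2], cent[, 1])
  tangential <- f[, 1] * (-sin(theta)) + f[, 2] * cos(theta)
  expect_true(all(tangential > 0.99))
})

test_that("degenerate gradients fall back to neighbors or warn", {
  m <- grid_mesh(5)
  expect_warning(f <- fiber_directions(m, rep(0.5, nrow(m$vertices))),
                 "degenerate")
  expect_true(all(attr(f, "degenerate")))
  expect_equal(max(abs(f)), 0)
})

test_that("label validation and mesh I/O round trip", {
  expect_error(leaflet_mesh(diag(3), rbind(c(1, 2, 3)),
                            list(tau1 = c(1, 2), tau2 = c(2, 3))),
               "disjoint")
  m <- generate_leaflet_mesh(5)
  off <- withr::local_tempfile(fileext = ".off")
  lab <- withr::local_tempfile(fileext = ".json")
  write_off(m, off)
  writeLines(jsonlite::toJSON(m$labels, auto_unbox = TRUE), lab)
  m2 <- read_off(off, lab)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(m2$triangles, m$triangles, ignore_attr = TRUE)
  expect_equal(m2$labels$n1, m$labels$n1)
  expect_equal(sort(unlist(m2$labels$tau2)), m$labels$tau2)

  vtk <- withr::local_tempfile(fileext = ".vtk")
  f <- fiber_directions(m, solve_fiber_potential(m, "FD2"))
  write_vtk(m, vtk, fibers = f)
  lines <- readLines(vtk)
  expect_true(any(grepl("^POLYGONS", lines)))
  expect_true(any(grepl("VECTORS fibers", lines)))
})
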