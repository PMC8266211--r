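#' Labelled triangulated leaflet surface
#'
#' A manifold triangulated surface with the boundary features needed by the
#' rule-based fiber constructions: the two commissure corner vertices
#' (\code{n1}, \code{n2}) and the two attachment-edge vertex sets
#' (\code{tau1}, \code{tau2}) where the leaflet joins the aortic wall, plus
#' optionally the free-edge vertex set.
#'
#' @param vertices n x 3 matrix of coordinates (cm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param labels list with elements \code{n1}, \code{n2} (single vertex ids)
#'   and \code{tau1}, \code{tau2} (disjoint vertex-id vectors); optional
#'   \code{free_edge}.
#' @return An object of class \code{leaflet_mesh}.
#' @export
leaflet_mesh <- function(vertices, triangles, labels = list()) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            min(triangles) >= 1, max(triangles) <= nrow(vertices))
  if (!is.null(labels$tau1) && !is.null(labels$tau2) &&
      length(intersect(labels$tau1, labels$tau2)) > 0) {
    stop("tau1 and tau2 label sets must be disjoint")
  }
  structure(list(vertices = vertices, triangles = triangles,
                 labels = labels),
            class = "leaflet_mesh")
}

#' @export
print.leaflet_mesh <- function(x, ...) {
  cat(sprintf("<leaflet_mesh> %d vertices, %d triangles, labels: %s\n",
              nrow(x$vertices), nrow(x$triangles),
              paste(names(x$labels), collapse = ", ")))
  invisible(x)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(cx^2)) / 2
}

triangle_normals <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cx / sqrt(rowSums(cx^2))
}

#' Cotangent-weight surface Laplacian
#'
#' Assembles the standard piecewise-linear finite-element (cotangent)
#' Laplacian of the triangulated surface: for interior edge \eqn{(i,j)}
#' shared by angles \eqn{\alpha, \beta} opposite the edge,
#' \eqn{L_{ij} = -(\cot\alpha + \cot\beta)/2}, diagonal entries make row
#' sums zero. Symmetric positive semi-definite for reasonable meshes.
#'
#' @param mesh \code{leaflet_mesh}.
#' @return Sparse symmetric \code{Matrix::dgCMatrix}.
#' @export
cotan_laplacian <- function(mesh) {
  stopifnot(inherits(mesh, "leaflet_mesh"))
  v <- mesh$vertices
  tr <- mesh$triangles
  areas <- triangle_areas(mesh)
  if (any(areas < 1e-14)) {
    stop("degenerate (zero-area) triangle index ",
         which(areas < 1e-14)[1])
  }
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  # for each local corner k the opposite edge is (k+1, k+2)
  for (k in 1:3) {
    a <- tr[, k]
    b <- tr[, (k %% 3) + 1]
    c <- tr[, ((k + 1) %% 3) + 1]
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    cosa <- rowSums(u * w)
    cxn <- sqrt(pmax(rowSums(u * u) * rowSums(w * w) - cosa^2, 0))
    cot <- cosa / pmax(cxn, 1e-300)
    half <- cot / 2
    ii <- c(ii, b, c); jj <- c(jj, c, b); ww <- c(ww, -half, -half)
  }
  n <- nrow(v)
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  Matrix::diag(L) <- -Matrix::rowSums(L)
  Matrix::forceSymmetric(L)
}

# solve L u = 0 with Dirichlet constraints (ids -> values) by row reduction
solve_harmonic <- function(mesh, ids, values) {
  L <- cotan_laplacian(mesh)
  n <- nrow(mesh$vertices)
  if (anyDuplicated(ids)) stop("duplicate Dirichlet constraint vertices")
  u <- numeric(n)
  u[ids] <- values
  free <- setdiff(seq_len(n), ids)
  if (length(free) > 0) {
    Lff <- L[free, free, drop = FALSE]
    rhs <- -L[free, ids, drop = FALSE] %*% u[ids]
    u[free] <- as.numeric(Matrix::solve(Lff, rhs))
  }
  res <- as.numeric(L[free, , drop = FALSE] %*% u)
  structure(list(u = u, residual = max(abs(res), 0)),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> %d vertices, range [%.3g, %.3g], residual %.2g\n",
              length(x$u), min(x$u), max(x$u), x$residual))
  invisible(x)
}

#' Harmonic potential for a fiber architecture
#'
#' Solves the surface Laplace problem defining one of the two rule-based
#' collagen architectures:
#' \describe{
#'   \item{FD1 (body-fitted)}{point Dirichlet constraints
#'     \eqn{u(n_1) = 1}, \eqn{u(n_2) = 0} at the two commissure corner
#'     vertices, natural (zero-flux) conditions elsewhere.}
#'   \item{FD2 (circumferential)}{Dirichlet values 0 on the attachment-edge
#'     set \eqn{\tau_1} and 1 on \eqn{\tau_2}, natural conditions on the
#'     rest of the boundary.}
#' }
#' The fiber direction field is the normalized surface gradient of
#' \code{u} (see \code{\link{fiber_directions}}).
#'
#' @param mesh \code{leaflet_mesh} with the labels the architecture needs.
#' @param arch "FD1" or "FD2".
#' @return A \code{scalar_field} with per-vertex values \code{u} in [0, 1]
#'   and the linear-solve residual.
#' @export
solve_fiber_potential <- function(mesh, arch = c("FD1", "FD2")) {
  arch <- match.arg(arch)
  stopifnot(inherits(mesh, "leaflet_mesh"))
  lb <- mesh$labels
  if (arch == "FD1") {
    if (is.null(lb$n1) || is.null(lb$n2)) {
      stop("FD1 requires corner labels n1 and n2")
    }
    if (lb$n1 == lb$n2) stop("n1 and n2 must differ")
    solve_harmonic(mesh, c(lb$n1, lb$n2), c(1, 0))
  } else {
    if (is.null(lb$tau1) || is.null(lb$tau2) ||
        length(lb$tau1) == 0 || length(lb$tau2) == 0) {
      stop("FD2 requires non-empty attachment labels tau1 and tau2")
    }
    if (length(intersect(lb$tau1, lb$tau2)) > 0) {
      stop("tau1 and tau2 must be disjoint")
    }
    solve_harmonic(mesh, c(lb$tau1, lb$tau2),
                   c(rep(0, length(lb$tau1)), rep(1, length(lb$tau2))))
  }
}

#' Per-triangle fiber directions from a scalar potential
#'
#' Computes the gradient of the piecewise-linear interpolant of \code{u}
#' on each triangle (constant per element, tangent to the triangle plane)
#' and normalizes it: \eqn{f = \nabla u / |\nabla u|}. Triangles whose
#' gradient magnitude falls below \code{1e-12 * range(u) / diameter} take
#' the area-weighted mean direction of their edge neighbors; if no
#' neighbor has a valid direction the triangle gets a zero vector and a
#' warning (flagged in the \code{degenerate} attribute).
#'
#' @param mesh \code{leaflet_mesh}.
#' @param field \code{scalar_field} (or bare numeric vector of vertex values).
#' @return m x 3 matrix of unit fiber vectors with logical attribute
#'   \code{degenerate} marking unresolvable triangles.
#' @export
fiber_directions <- function(mesh, field) {
  stopifnot(inherits(mesh, "leaflet_mesh"))
  u <- if (inherits(field, "scalar_field")) field$u else as.numeric(field)
  v <- mesh$vertices
  tr <- mesh$triangles
  m <- nrow(tr)
  areas <- triangle_areas(mesh)
  nrm <- triangle_normals(mesh)

  # grad of linear shape functions: (1/2A) sum_i u_i (N x e_i),
  # e_i the edge opposite vertex i with consistent orientation
  g <- matrix(0, m, 3)
  for (k in 1:3) {
    i <- tr[, k]
    eop <- v[tr[, ((k + 1) %% 3) + 1], , drop = FALSE] -
           v[tr[, (k %% 3) + 1], , drop = FALSE]
    ncross <- cbind(nrm[, 2] * eop[, 3] - nrm[, 3] * eop[, 2],
                    nrm[, 3] * eop[, 1] - nrm[, 1] * eop[, 3],
                    nrm[, 1] * eop[, 2] - nrm[, 2] * eop[, 1])
    g <- g + u[i] * ncross
  }
  g <- g / (2 * areas)

  mag <- sqrt(rowSums(g^2))
  diam <- max(stats::dist(rbind(apply(v, 2, min), apply(v, 2, max))))
  tol <- 1e-12 * diff(range(u)) / max(diam, 1e-300)
  ok <- mag > max(tol, 1e-300)
  f <- g
  f[ok, ] <- g[ok, , drop = FALSE] / mag[ok]
  f[!ok, ] <- 0

  if (any(!ok)) {
    adj <- triangle_adjacency(tr)
    for (t in which(!ok)) {
      nb <- adj[[t]]
      nb <- nb[ok[nb]]
      if (length(nb) == 0) next
      avg <- colSums(f[nb, , drop = FALSE] * areas[nb])
      nav <- sqrt(sum(avg^2))
      if (nav > 1e-300) {
        # project onto this triangle's plane, renormalize
        avg <- avg - sum(avg * nrm[t, ]) * nrm[t, ]
        nav <- sqrt(sum(avg^2))
        if (nav > 1e-300) {
          f[t, ] <- avg / nav
          ok[t] <- TRUE
        }
      }
    }
    if (any(!ok)) {
      warning(sum(!ok), " triangle(s) have degenerate gradient and no ",
              "valid neighbor; direction set to zero")
    }
  }
  attr(f, "degenerate") <- !ok
  f
}

triangle_adjacency <- function(tr) {
  m <- nrow(tr)
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- c(edge_key(tr[, 1], tr[, 2]),
            edge_key(tr[, 2], tr[, 3]),
            edge_key(tr[, 3], tr[, 1]))
  tri_of <- rep(seq_len(m), 3)
  sp <- split(tri_of, keys)
  adj <- vector("list", m)
  for (g in sp) {
    if (length(g) == 2) {
      adj[[g[1]]] <- c(adj[[g[1]]], g[2])
      adj[[g[2]]] <- c(adj[[g[2]]], g[1])
    }
  }
  adj
}

#' Boundary vertices of a triangulated surface
#'
#' Vertices incident to an edge used by exactly one triangle.
#'
#' @param mesh \code{leaflet_mesh}.
#' @return Integer vector of vertex indices.
#' @export
boundary_vertices <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  bkeys <- names(tab)[tab == 1]
  if (length(bkeys) == 0) return(integer(0))
  sort(unique(as.integer(unlist(strsplit(bkeys, " ")))))
}

#' Write a mesh (with optional per-triangle fiber vectors) as legacy VTK
#'
#' ASCII legacy VTK POLYDATA with triangle cells; fiber vectors are written
#' as CELL_DATA \code{VECTORS fibers}.
#'
#' @param mesh \code{leaflet_mesh}.
#' @param path output file.
#' @param fibers optional m x 3 fiber matrix.
#' @export
write_vtk <- function(mesh, path, fibers = NULL) {
  stopifnot(inherits(mesh, "leaflet_mesh"))
  v <- mesh$vertices
  tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "leaflet surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  utils::write.table(format(v, digits = 12, scientific = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4L * nrow(tr)), con)
  utils::write.table(cbind(3L, tr - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (!is.null(fibers)) {
    writeLines(c(sprintf("CELL_DATA %d", nrow(tr)),
                 "VECTORS fibers double"), con)
    utils::write.table(format(fibers, digits = 12, scientific = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a mesh in OFF format
#'
#' @param mesh \code{leaflet_mesh}.
#' @param path output file.
#' @export
write_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "leaflet_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", sprintf("%d %d 0", nrow(mesh$vertices),
                              nrow(mesh$triangles))), con)
  utils::write.table(format(mesh$vertices, digits = 12), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an OFF mesh, optionally with a JSON label sidecar
#'
#' The sidecar holds \code{\{"n1": id, "n2": id, "tau1": [...],
#' "tau2": [...]\}} with 1-based vertex indices.
#'
#' @param path OFF file.
#' @param labels_path optional JSON sidecar.
#' @return A \code{leaflet_mesh}.
#' @export
read_off <- function(path, labels_path = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtx <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fl <- lapply(lines[(3 + nv):(2 + nv + nf)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(vapply(fl, `[`, integer(1), 1) != 3L)) {
    stop("only triangle faces supported")
  }
  tri <- do.call(rbind, lapply(fl, function(x) x[2:4] + 1L))
  labels <- list()
  if (!is.null(labels_path)) {
    labels <- jsonlite::fromJSON(labels_path)
  }
  leaflet_mesh(vtx, tri, labels)
}

#' Export per-triangle fibers as CSV
#'
#' Columns \code{triangle_id,fx,fy,fz}.
#'
#' @param fibers m x 3 matrix from \code{\link{fiber_directions}}.
#' @param path output file.
#' @export
write_fibers_csv <- function(fibers, path) {
  out <- data.frame(triangle_id = seq_len(nrow(fibers)),
                    fx = fibers[, 1], fy = fibers[, 2], fz = fibers[, 3])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
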