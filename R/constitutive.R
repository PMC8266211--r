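#' Material parameter sets for the three leaflet constitutive laws
#'
#' Constructs a validated parameter set for one of three incompressible,
#' fiber-reinforced hyperelastic strain-energy functions commonly used for
#' aortic valve leaflet tissue:
#' \describe{
#'   \item{W1}{\eqn{C_{10}(e^{C_{01}(I_1-3)}-1) +
#'     \frac{k_1}{2k_2}[e^{k_2(I_4-1)^2}-1]} — exponential isotropic matrix
#'     plus exponential fiber reinforcement.}
#'   \item{W2}{\eqn{\mu(I_1-3) + c_0[e^{c_1(I_1-3)^2+c_2(I_4-1)^4}-1]} —
#'     neo-Hookean matrix plus a coupled exponential in both invariants.}
#'   \item{W3}{\eqn{C_1(I_1-3) + \frac{a}{2b}[e^{b(I_4-1)^2}-1]} — linear
#'     (neo-Hookean) cross-fiber response plus exponential fiber term.}
#' }
#' \eqn{I_1 = \mathrm{tr}(C)} and \eqn{I_4 = f_0\cdot(C f_0)} are invariants
#' of the right Cauchy–Green tensor \eqn{C = F^T F}; \eqn{f_0} is the
#' reference fiber direction. Stress-like parameters (C10, k1, mu, c0, C1, a)
#' are in kPa; the exponents (C01, k2, c1, c2, b) are dimensionless.
#'
#' @param law one of "W1", "W2", "W3".
#' @param ... named parameters for the law: W1 needs C10, C01, k1, k2;
#'   W2 needs mu, c0, c1, c2; W3 needs C1, a, b. All must be >= 0 (the
#'   lower bound used in calibration).
#' @return An object of class \code{material_params}.
#' @examples
#' material_params("W3", C1 = 19.59, a = 12.94, b = 77.79)
#' @export
material_params <- function(law = c("W1", "W2", "W3"), ...) {
  law <- match.arg(law)
  p <- list(...)
  if (length(p) == 1L && is.list(p[[1]]) && is.null(names(p))) p <- p[[1]]
  need <- law_param_names(law)
  if (!setequal(names(p), need)) {
    stop(sprintf("law %s requires parameters {%s}, got {%s}",
                 law, paste(need, collapse = ", "),
                 paste(names(p), collapse = ", ")))
  }
  vals <- vapply(p[need], function(x) as.numeric(x)[1], numeric(1))
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all material parameters must be finite and >= 0")
  }
  structure(list(law = law, params = vals), class = "material_params")
}

law_param_names <- function(law) {
  switch(law,
    W1 = c("C10", "C01", "k1", "k2"),
    W2 = c("mu", "c0", "c1", "c2"),
    W3 = c("C1", "a", "b"),
    stop("unknown law: ", law))
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("<material_params> law %s (kPa units)\n", x$law))
  print(x$params)
  invisible(x)
}

#' Calibrated porcine leaflet parameters
#'
#' Published averaged parameter values for each law, calibrated to planar
#' biaxial tests of porcine aortic valve leaflets. Used as realistic
#' defaults for simulation studies and as ground truth in parameter-recovery
#' experiments.
#'
#' @param law one of "W1", "W2", "W3".
#' @return A \code{material_params} object.
#' @export
porcine_leaflet_params <- function(law = c("W1", "W2", "W3")) {
  law <- match.arg(law)
  switch(law,
    W1 = material_params("W1", C10 = 1.21, C01 = 7.99, k1 = 24.23, k2 = 57.62),
    W2 = material_params("W2", mu = 1.18, c0 = 55.04, c1 = 8.08, c2 = 54.00),
    W3 = material_params("W3", C1 = 19.59, a = 12.94, b = 77.79))
}

#' Deformation state from a general deformation gradient
#'
#' Builds the kinematic quantities used by the constitutive laws: the right
#' and left Cauchy–Green tensors \eqn{C = F^T F} and \eqn{B = F F^T}, the
#' invariants \eqn{I_1 = \mathrm{tr}(C)} and \eqn{I_4 = f_0\cdot(C f_0)},
#' the Green strain \eqn{E = (C - I)/2}, the Jacobian \eqn{J = \det F} and
#' the deformed (push-forward) fiber vector \eqn{f = F f_0}.
#'
#' @param F 3x3 deformation gradient (dimensionless).
#' @param f0 reference fiber direction; normalized internally, must be
#'   non-zero.
#' @return An object of class \code{deformation_state}.
#' @export
deformation_state <- function(F, f0 = c(1, 0, 0)) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3L, 3L)), all(is.finite(F)))
  f0 <- as.numeric(f0)
  n0 <- sqrt(sum(f0^2))
  if (!is.finite(n0) || n0 == 0) stop("f0 must be a non-zero 3-vector")
  f0 <- f0 / n0
  C <- crossprod(F)          # F^T F
  B <- tcrossprod(F)         # F F^T
  I4 <- drop(f0 %*% C %*% f0)
  if (I4 <= 0) stop("I4 must be positive")
  structure(list(
    F = F, f0 = f0, J = det(F), C = C, B = B,
    I1 = sum(diag(C)), I4 = I4,
    E = (C - diag(3)) / 2, f = drop(F %*% f0)
  ), class = "deformation_state")
}

#' Incompressible planar-biaxial kinematics
#'
#' Deformation state for a planar biaxial stretch with the fiber
#' (circumferential) direction along the first test axis:
#' \eqn{F = \mathrm{diag}(\lambda_1, \lambda_2, 1/(\lambda_1\lambda_2))},
#' so that \eqn{J = 1} exactly and \eqn{I_4 = \lambda_1^2}.
#'
#' @param lambda1 stretch along the fiber direction (> 0).
#' @param lambda2 stretch along the cross-fiber direction (> 0).
#' @return A \code{deformation_state}.
#' @export
deformation_from_stretches <- function(lambda1, lambda2) {
  if (!is.finite(lambda1) || !is.finite(lambda2) ||
      lambda1 <= 0 || lambda2 <= 0) {
    stop("stretches must be positive and finite")
  }
  deformation_state(diag(c(lambda1, lambda2, 1 / (lambda1 * lambda2))),
                    f0 = c(1, 0, 0))
}

# exponent guard: the exponential laws overflow double precision long before
# the optimizer's bound box is exhausted; cap so the loss stays finite and
# steeply increasing instead of NaN.
.exp_cap <- function(x) exp(pmin(x, 700))

#' Strain-energy density
#'
#' Evaluates the strain-energy function of the given law at a deformation
#' state. All three laws vanish in the reference configuration
#' (\eqn{I_1 = 3}, \eqn{I_4 = 1}).
#'
#' @param params \code{material_params}.
#' @param state \code{deformation_state}.
#' @return Energy density in kPa.
#' @export
strain_energy <- function(params, state) {
  stopifnot(inherits(params, "material_params"),
            inherits(state, "deformation_state"))
  p <- params$params
  i1 <- state$I1 - 3
  i4 <- state$I4 - 1
  switch(params$law,
    W1 = p[["C10"]] * (.exp_cap(p[["C01"]] * i1) - 1) +
         fiber_energy_w1(p[["k1"]], p[["k2"]], i4),
    W2 = p[["mu"]] * i1 +
         p[["c0"]] * (.exp_cap(p[["c1"]] * i1^2 + p[["c2"]] * i4^4) - 1),
    W3 = p[["C1"]] * i1 + fiber_energy_w1(p[["a"]], p[["b"]], i4))
}

# k1/(2 k2) [exp(k2 x^2) - 1], with the k2 -> 0 limit k1 x^2 / 2
fiber_energy_w1 <- function(k1, k2, x) {
  if (k2 < 1e-12) return(k1 * x^2 / 2)
  k1 / (2 * k2) * (.exp_cap(k2 * x^2) - 1)
}

# scalar response coefficients: sigma = -p I + iso * B + fib * f (x) f,
# with iso = 2 dW/dI1 and fib = 2 dW/dI4 and f = F f0 (unnormalized).
stress_coefficients <- function(params, I1, I4) {
  p <- params$params
  i1 <- I1 - 3
  i4 <- I4 - 1
  switch(params$law,
    W1 = list(iso = 2 * p[["C10"]] * p[["C01"]] * .exp_cap(p[["C01"]] * i1),
              fib = 2 * p[["k1"]] * i4 * .exp_cap(p[["k2"]] * i4^2)),
    W2 = {
      e <- .exp_cap(p[["c1"]] * i1^2 + p[["c2"]] * i4^4)
      list(iso = 2 * p[["mu"]] + 4 * p[["c0"]] * p[["c1"]] * i1 * e,
           fib = 8 * p[["c0"]] * p[["c2"]] * i4^3 * e)
    },
    W3 = list(iso = 2 * p[["C1"]],
              fib = 2 * p[["a"]] * i4 * .exp_cap(p[["b"]] * i4^2)))
}

#' Cauchy stress of an incompressible fiber-reinforced material
#'
#' \eqn{\sigma = -p I + 2 W_{,I_1} B + 2 W_{,I_4} f \otimes f} with
#' \eqn{f = F f_0}. The Lagrange multiplier \eqn{p} enforcing
#' incompressibility must be supplied (it is set by the boundary-value
#' problem, e.g. by the plane-stress condition in a biaxial test).
#'
#' @param params \code{material_params}.
#' @param state \code{deformation_state}.
#' @param p Lagrange-multiplier pressure (kPa), finite scalar.
#' @return An object of class \code{stress_state} with fields \code{sigma}
#'   (symmetric 3x3, kPa) and \code{p}.
#' @export
cauchy_stress <- function(params, state, p = 0) {
  stopifnot(inherits(params, "material_params"),
            inherits(state, "deformation_state"),
            is.finite(p))
  co <- stress_coefficients(params, state$I1, state$I4)
  f <- state$f
  sigma <- -p * diag(3) + co$iso * state$B + co$fib * tcrossprod(f)
  sigma <- (sigma + t(sigma)) / 2
  structure(list(sigma = sigma, p = p), class = "stress_state")
}

#' Convert Cauchy stress to first Piola-Kirchhoff stress
#'
#' Inverts the push-forward relation \eqn{\sigma = J^{-1} P F^T}:
#' \eqn{P = J \sigma F^{-T}}.
#'
#' @param state \code{deformation_state} with \eqn{J > 0}.
#' @param sigma 3x3 Cauchy stress (kPa).
#' @return 3x3 first Piola-Kirchhoff tensor (kPa).
#' @export
piola_from_cauchy <- function(state, sigma) {
  stopifnot(inherits(state, "deformation_state"))
  if (!is.finite(state$J) || state$J <= 0) stop("requires det(F) > 0")
  sigma <- as.matrix(sigma)
  state$J * sigma %*% t(solve(state$F))
}

#' Convert first Piola-Kirchhoff stress to Cauchy stress
#'
#' @param state \code{deformation_state} with \eqn{J > 0}.
#' @param P 3x3 first Piola-Kirchhoff tensor (kPa).
#' @return 3x3 Cauchy stress (kPa).
#' @export
cauchy_from_piola <- function(state, P) {
  stopifnot(inherits(state, "deformation_state"))
  if (!is.finite(state$J) || state$J <= 0) stop("requires det(F) > 0")
  (as.matrix(P) %*% t(state$F)) / state$J
}

#' Plane-stress planar-biaxial response
#'
#' Analytical stretch-stress relation of an incompressible sheet with
#' in-plane fibers along the first axis, stretched biaxially. With
#' \eqn{\lambda_3 = 1/(\lambda_1\lambda_2)} and the plane-stress condition
#' \eqn{\sigma_{33} = 0}, the incompressibility pressure is eliminated as
#' \eqn{p = \mathrm{iso}\cdot\lambda_3^2}, giving
#' \deqn{\sigma_{11} = \mathrm{iso}(\lambda_1^2 - \lambda_3^2) +
#'       \mathrm{fib}\,\lambda_1^2, \quad
#'       \sigma_{22} = \mathrm{iso}(\lambda_2^2 - \lambda_3^2).}
#' Vectorized over stretches.
#'
#' @param params \code{material_params}.
#' @param lambda1,lambda2 stretch vectors (> 0), recycled to equal length.
#' @return A data.frame with columns lambda1, lambda2, sigma11, sigma22 (kPa).
#' @export
planar_biaxial_stress <- function(params, lambda1, lambda2) {
  stopifnot(inherits(params, "material_params"))
  n <- max(length(lambda1), length(lambda2))
  lambda1 <- rep_len(as.numeric(lambda1), n)
  lambda2 <- rep_len(as.numeric(lambda2), n)
  if (any(!is.finite(lambda1)) || any(!is.finite(lambda2)) ||
      any(lambda1 <= 0) || any(lambda2 <= 0)) {
    stop("stretches must be positive and finite")
  }
  m <- biaxial_model_stress(params, lambda1, lambda2)
  data.frame(lambda1 = lambda1, lambda2 = lambda2,
             sigma11 = m$sigma11, sigma22 = m$sigma22)
}

# allocation-lean core of planar_biaxial_stress (hot path of the fitting
# loss); stress_coefficients is elementwise, so plain vector arithmetic
biaxial_model_stress <- function(params, lambda1, lambda2) {
  l3sq <- 1 / (lambda1 * lambda2)^2
  co <- stress_coefficients(params, lambda1^2 + lambda2^2 + l3sq, lambda1^2)
  list(sigma11 = co$iso * (lambda1^2 - l3sq) + co$fib * lambda1^2,
       sigma22 = co$iso * (lambda2^2 - l3sq))
}

#' Fiber strain
#'
#' Green strain projected on the reference fiber direction,
#' \eqn{f_0\cdot(E f_0) = (I_4 - 1)/2}.
#'
#' @param state \code{deformation_state}.
#' @return Dimensionless scalar.
#' @export
fiber_strain <- function(state) {
  stopifnot(inherits(state, "deformation_state"))
  drop(state$f0 %*% state$E %*% state$f0)
}

#' Fiber stress
#'
#' Normal Cauchy stress along the deformed fiber direction,
#' \eqn{\hat f\cdot(\sigma \hat f)} with \eqn{\hat f = F f_0 / |F f_0|}.
#' The deformed direction is normalized so the value is a true normal
#' stress (traction component) rather than being scaled by the squared
#' fiber stretch.
#'
#' @param state \code{deformation_state}.
#' @param sigma 3x3 Cauchy stress (kPa) or a \code{stress_state}.
#' @return Stress in kPa.
#' @export
fiber_stress <- function(state, sigma) {
  stopifnot(inherits(state, "deformation_state"))
  if (inherits(sigma, "stress_state")) sigma <- sigma$sigma
  f <- state$f
  nf <- sqrt(sum(f^2))
  if (nf < 1e-14) stop("deformed fiber direction has zero length")
  fh <- f / nf
  drop(fh %*% as.matrix(sigma) %*% fh)
}

#' Serialize material parameters to JSON
#'
#' @param params \code{material_params}.
#' @param path optional file path; if NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
material_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "material_params"))
  js <- jsonlite::toJSON(list(law = params$law,
                              params = as.list(params$params),
                              units = "kPa"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read material parameters from JSON
#'
#' @param path file path or JSON string.
#' @return A \code{material_params} object.
#' @export
material_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(material_params, c(list(law = x$law), as.list(x$params)))
}

#' Export stretch-stress curves as CSV
#'
#' Writes columns \code{lambda1,lambda2,sigma11_kPa,sigma22_kPa}.
#'
#' @param curve data.frame as returned by \code{\link{planar_biaxial_stress}}.
#' @param path output file.
#' @export
write_stress_curve_csv <- function(curve, path) {
  out <- data.frame(lambda1 = curve$lambda1, lambda2 = curve$lambda2,
                    sigma11_kPa = curve$sigma11, sigma22_kPa = curve$sigma22)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
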