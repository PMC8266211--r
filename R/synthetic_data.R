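# mmHg -> kPa (1 mmHg = 0.13332 kPa to the precision used throughout)
MMHG_TO_KPA <- 0.13332

#' Physiological target stress from Laplace's law
#'
#' Thin spherical shell estimate of the peak membrane stress a leaflet
#' carries, \eqn{\sigma = P r / (2 h)}, used to choose the peak stress of
#' the biaxial loading protocol. Defaults: mean radius of curvature 2 cm,
#' transvalvular pressure 120 mmHg, leaflet thickness 0.04 cm, giving
#' about 400 kPa.
#'
#' @param radius mean radius of curvature (cm).
#' @param pressure transvalvular pressure (mmHg).
#' @param thickness leaflet thickness (cm).
#' @return Stress in kPa.
#' @export
laplace_target_stress <- function(radius = 2, pressure = 120,
                                  thickness = 0.04) {
  stopifnot(radius > 0, pressure > 0, thickness > 0)
  MMHG_TO_KPA * pressure * radius / (2 * thickness)
}

#' Biaxial loading protocol
#'
#' Protocol description for the synthetic biaxial generator: equibiaxial
#' stress control (1:1 stress ratio in the two directions, the standard
#' protocol for anisotropy characterization) or equibiaxial stretch
#' control; peak stress from Laplace's law by default; optional
#' multiplicative Gaussian measurement noise.
#'
#' @param mode "equibiaxial-stress" (1:1 stress ratio) or
#'   "equibiaxial-stretch".
#' @param peak_stress peak target stress (kPa).
#' @param n_points number of load levels (>= 10).
#' @param noise_cv multiplicative noise coefficient of variation (>= 0).
#' @return An object of class \code{biaxial_protocol}.
#' @export
biaxial_protocol <- function(mode = c("equibiaxial-stress",
                                      "equibiaxial-stretch"),
                             peak_stress = laplace_target_stress(),
                             n_points = 25, noise_cv = 0) {
  mode <- match.arg(mode)
  stopifnot(peak_stress > 0, n_points >= 10, noise_cv >= 0)
  structure(list(mode = mode, peak_stress = peak_stress,
                 n_points = as.integer(n_points), noise_cv = noise_cv),
            class = "biaxial_protocol")
}

# solve planar_biaxial_stress(params, l1, l2) = (s, s) by damped Newton
# with finite-difference Jacobian; start from the previous load level
solve_equibiaxial_stretch <- function(params, s, start = c(1.001, 1.001),
                                      tol = 1e-10, maxit = 100) {
  resid <- function(l) {
    m <- planar_biaxial_stress(params, l[1], l[2])
    c(m$sigma11 - s, m$sigma22 - s)
  }
  l <- pmax(start, 1 + 1e-9)
  r <- resid(l)
  for (it in seq_len(maxit)) {
    if (max(abs(r)) < tol) return(l)
    h <- 1e-7
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      lp <- l; lp[j] <- lp[j] + h
      lm <- l; lm[j] <- max(lm[j] - h, 1e-9)
      J[, j] <- (resid(lp) - resid(lm)) / (lp[j] - lm[j])
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      stop(sprintf("equibiaxial solve failed at stress level %.4g kPa", s))
    }
    alpha <- 1
    repeat {
      ln <- l - alpha * step
      if (all(ln > 1e-6)) {
        rn <- resid(ln)
        if (all(is.finite(rn)) &&
            (sum(rn^2) < sum(r^2) || alpha < 1e-6)) break
      }
      alpha <- alpha / 2
      if (alpha < 1e-12) {
        stop(sprintf("equibiaxial solve stalled at stress level %.4g kPa", s))
      }
    }
    l <- ln; r <- rn
  }
  if (max(abs(r)) > 1e-6) {
    stop(sprintf("equibiaxial solve did not converge at %.4g kPa", s))
  }
  l
}

#' Generate a synthetic biaxial dataset
#'
#' Emulates a stress-controlled planar biaxial test of a leaflet sample
#' with the given material. In equibiaxial-stress mode the stretches at
#' each target stress level \eqn{s} are found by solving
#' \eqn{\sigma_{11}(\lambda_1, \lambda_2) = \sigma_{22}(\lambda_1,
#' \lambda_2) = s} (2D damped Newton with continuation across levels); in
#' equibiaxial-stretch mode \eqn{\lambda_1 = \lambda_2} is ramped directly.
#' Multiplicative Gaussian noise \eqn{(1 + cv\,\epsilon)} is then applied
#' to the stresses.
#'
#' @param params \code{material_params} of the generating law.
#' @param proto \code{biaxial_protocol}.
#' @param seed integer seed (noise reproducibility).
#' @param sample_id dataset identifier.
#' @return A \code{biaxial_dataset}.
#' @export
generate_biaxial <- function(params, proto = biaxial_protocol(),
                             seed = NULL, sample_id = "synthetic") {
  stopifnot(inherits(params, "material_params"),
            inherits(proto, "biaxial_protocol"))
  n <- proto$n_points
  if (proto$mode == "equibiaxial-stress") {
    levels <- seq(proto$peak_stress / n, proto$peak_stress, length.out = n)
    l1 <- numeric(n); l2 <- numeric(n)
    start <- c(1.001, 1.001)
    for (i in seq_len(n)) {
      start <- solve_equibiaxial_stretch(params, levels[i], start)
      l1[i] <- start[1]; l2[i] <- start[2]
    }
    m <- planar_biaxial_stress(params, l1, l2)
  } else {
    # stretch ramp chosen to span roughly the same stress range:
    # walk the equal-stretch path until sigma11 reaches the peak
    lmax <- 1.0
    repeat {
      lmax <- lmax + 0.005
      s11 <- planar_biaxial_stress(params, lmax, lmax)$sigma11
      if (s11 >= proto$peak_stress || lmax > 2) break
    }
    lam <- seq(1 + (lmax - 1) / n, lmax, length.out = n)
    m <- planar_biaxial_stress(params, lam, lam)
  }
  s11 <- m$sigma11; s22 <- m$sigma22
  if (proto$noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    s11 <- s11 * (1 + proto$noise_cv * stats::rnorm(n))
    s22 <- s22 * (1 + proto$noise_cv * stats::rnorm(n))
  }
  biaxial_dataset(m$lambda1, m$lambda2, s11, s22, sample_id = sample_id)
}

#' Surrogate cardiac-cycle parameters
#'
#' Configuration of the lumped valve-Windkessel surrogate that stands in
#' for full fluid-structure simulation output. The left-ventricular
#' pressure is a smooth analytic pulse (smoothstep rise, plateau, fall);
#' the valve is a quasi-static orifice whose open area follows a
#' prescribed opening function, with flow
#' \eqn{Q = 51.6\,A(t)\sqrt{|\Delta P|}\,\mathrm{sign}(\Delta P)} coupled
#' implicitly to the three-element Windkessel afterload; a small leak
#' conductance acts after full closure. Defaults give a 0.8 s cycle with
#' forward volume, regurgitation and pressure gradients in the
#' physiological range of valve FSI studies.
#'
#' @param cycle_s cycle length (s).
#' @param dt sampling step (s).
#' @param p_dia,p_sys diastolic baseline and systolic peak LV pressure
#'   (mmHg).
#' @param t_rise0,t_rise1 LV pressure rise window (s).
#' @param t_fall0,t_fall1 LV pressure fall window (s).
#' @param a_max maximal open orifice area (cm^2).
#' @param t_open0,t_open1 valve opening ramp window (s).
#' @param t_close0,t_close1 valve closing ramp window (s).
#' @param leak_coeff leak conductance after closure (mL/s per sqrt(mmHg)).
#' @param wk \code{windkessel_params} afterload.
#' @return An object of class \code{surrogate_cycle_params}.
#' @export
surrogate_cycle_params <- function(cycle_s = 0.8, dt = 5e-4,
                                   p_dia = 10, p_sys = 115,
                                   t_rise0 = 0.05, t_rise1 = 0.15,
                                   t_fall0 = 0.32, t_fall1 = 0.43,
                                   a_max = 3.4,
                                   t_open0 = 0.06, t_open1 = 0.14,
                                   t_close0 = 0.25, t_close1 = 0.41,
                                   leak_coeff = 0.35,
                                   wk = windkessel_params()) {
  stopifnot(cycle_s > 0, dt > 0, a_max >= 0, leak_coeff >= 0,
            inherits(wk, "windkessel_params"))
  structure(as.list(environment()), class = "surrogate_cycle_params")
}

smoothstep <- function(t, t0, t1) {
  x <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  x * x * (3 - 2 * x)
}

# positive root of q^2 + c^2 Rc q - c^2 dp = 0 (orifice in series with Rc)
orifice_flow <- function(c_coef, dp, Rc) {
  if (dp <= 0 || c_coef <= 0) return(0)
  (-c_coef^2 * Rc + sqrt(c_coef^4 * Rc^2 + 4 * c_coef^2 * dp)) / 2
}

#' Generate a surrogate transvalvular cycle waveform
#'
#' Runs the quasi-static orifice/Windkessel surrogate over one cycle and
#' returns a fully populated \code{\link{waveform}}: flow, LV and aortic
#' pressures (near-valve channels aliased to them) and event times from
#' the threshold detector. Deterministic given the seed; the seed only
#' perturbs nothing by default (\code{noise_cv = 0}) but seeds the optional
#' multiplicative measurement noise on Q.
#'
#' @param sp \code{surrogate_cycle_params}.
#' @param seed integer seed.
#' @param noise_cv optional multiplicative noise on the flow channel.
#' @return A \code{waveform} with events set.
#' @export
generate_waveform <- function(sp = surrogate_cycle_params(), seed = NULL,
                              noise_cv = 0) {
  stopifnot(inherits(sp, "surrogate_cycle_params"))
  t <- seq(0, sp$cycle_s, by = sp$dt)
  n <- length(t)
  p_lv <- sp$p_dia + (sp$p_sys - sp$p_dia) *
    (smoothstep(t, sp$t_rise0, sp$t_rise1) -
     smoothstep(t, sp$t_fall0, sp$t_fall1))
  phi <- smoothstep(t, sp$t_open0, sp$t_open1) -
         smoothstep(t, sp$t_close0, sp$t_close1)
  area <- sp$a_max * phi

  Q <- numeric(n)
  Pwk <- numeric(n)
  Pwk[1] <- sp$wk$Pwk0
  for (i in seq_len(n)) {
    dp <- p_lv[i] - Pwk[i]
    c_coef <- 51.6 * area[i]
    if (dp >= 0) {
      Q[i] <- orifice_flow(c_coef, dp, sp$wk$Rc)
    } else {
      c_rev <- c_coef + sp$leak_coeff
      Q[i] <- -orifice_flow(c_rev, -dp, sp$wk$Rc)
    }
    if (i < n) Pwk[i + 1] <- wk_step(sp$wk, Pwk[i], Q[i], t[i + 1] - t[i])
  }
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    Q <- Q * (1 + noise_cv * stats::rnorm(n))
  }
  p_ao <- wk_outlet_pressure(sp$wk, Pwk, Q)
  w <- waveform(t, Q, P_lv = p_lv, P_ao = p_ao)
  if (max(Q) > 0) w <- detect_events(w) else {
    w$events <- list(t_bs = t[1], t_es = t[2], t_close = t[2],
                     t_cycle_end = t[n])
  }
  w
}

#' Generate a labelled semi-lunar leaflet mesh
#'
#' Idealized aortic valve leaflet surface patch: the attachment edge is a
#' U-shaped arc on a cylinder (the aortic tube, default inner radius
#' 1.3 cm), the free edge bows toward the tube axis for coaptation, and
#' the surface interpolates between them. Labels: \code{n1}/\code{n2} the
#' two commissure corners (free edge meets attachment), \code{tau1}/
#' \code{tau2} the two attachment halves (center column excluded so the
#' sets are disjoint), \code{free_edge} the free-edge vertices.
#'
#' @param resolution number of subdivisions across the leaflet (>= 4);
#'   the mesh has (2*resolution+1) x (resolution+1) vertices.
#' @param radius tube inner radius (cm).
#' @param height attachment sag depth (cm).
#' @param arc_deg circumferential span of the attachment (degrees).
#' @return A \code{leaflet_mesh}.
#' @export
generate_leaflet_mesh <- function(resolution = 12, radius = 1.3,
                                  height = 1.0, arc_deg = 110) {
  stopifnot(resolution >= 4, radius > 0, height > 0)
  ns <- 2L * as.integer(resolution) + 1L   # circumferential vertices
  nt <- as.integer(resolution) + 1L        # attachment -> free edge
  s <- seq(-1, 1, length.out = ns)
  tt <- seq(0, 1, length.out = nt)
  thm <- arc_deg / 2 * pi / 180

  idx <- function(i, j) (j - 1L) * ns + i  # i over s, j over t
  V <- matrix(0, ns * nt, 3)
  for (j in seq_len(nt)) {
    for (i in seq_len(ns)) {
      si <- s[i]; tj <- tt[j]
      theta <- si * thm
      # radial pullback toward the axis along the free edge for coaptation
      r <- radius * ((1 - tj) + tj * (0.15 + 0.85 * abs(si)))
      z_att <- -height * (1 - si^2)
      z_free <- 0.3 * height - 0.1 * height * (1 - si^2)
      z <- (1 - tj) * z_att + tj * z_free
      V[idx(i, j), ] <- c(r * sin(theta), r * cos(theta), z)
    }
  }
  tris <- matrix(0L, 2L * (ns - 1L) * (nt - 1L), 3)
  k <- 0L
  for (j in seq_len(nt - 1L)) {
    for (i in seq_len(ns - 1L)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c2 <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      tris[k + 1L, ] <- c(a, b, c2)
      tris[k + 2L, ] <- c(a, c2, d)
      k <- k + 2L
    }
  }
  mid <- (ns + 1L) %/% 2L
  labels <- list(
    n1 = idx(1L, nt),
    n2 = idx(ns, nt),
    tau1 = c(vapply(seq_len(nt - 1L), function(j) idx(1L, j), integer(1)),
             vapply(seq_len(mid - 1L), function(i) idx(i, 1L), integer(1))),
    tau2 = c(vapply(seq_len(nt - 1L), function(j) idx(ns, j), integer(1)),
             vapply(seq((mid + 1L), ns), function(i) idx(i, 1L),
                    integer(1))),
    free_edge = vapply(seq_len(ns), function(i) idx(i, nt), integer(1))
  )
  labels$tau1 <- sort(unique(labels$tau1))
  labels$tau2 <- sort(unique(labels$tau2))
  leaflet_mesh(V, tris, labels)
}
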