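#' Transvalvular cycle waveform
#'
#' Time series over (at least) one cardiac cycle of the transvalvular flow
#' rate and the pressures needed by the hemodynamic indices, together with
#' the cycle event times: begin and end of systole (\code{t_bs},
#' \code{t_es}), full valve closure (\code{t_close}) and cycle end
#' (\code{t_cycle_end}).
#'
#' Pressure channels: \code{P_lv}/\code{P_ao} are the inlet/outlet pressures
#' (used for the energy loss), \code{P_nlv}/\code{P_nao} the near-valve
#' pressures on the ventricular and aortic sides (used for the mean
#' transvalvular gradient); if the near-valve channels are missing they
#' default to the inlet/outlet ones.
#'
#' @param t strictly increasing times (s).
#' @param Q flow (mL/s), positive toward the aorta.
#' @param P_lv,P_ao inlet and outlet pressures (mmHg), optional.
#' @param P_nlv,P_nao near-valve pressures (mmHg), optional.
#' @param events list with t_bs, t_es, t_close, t_cycle_end (s); may be
#'   omitted and detected later with \code{\link{detect_events}}.
#' @return An object of class \code{waveform}.
#' @export
waveform <- function(t, Q, P_lv = NULL, P_ao = NULL,
                     P_nlv = NULL, P_nao = NULL, events = NULL) {
  t <- as.numeric(t); Q <- as.numeric(Q)
  stopifnot(length(t) == length(Q), length(t) >= 2)
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing")
  chk <- function(x, nm) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) != length(t)) stop(nm, " must match length of t")
    x
  }
  P_lv <- chk(P_lv, "P_lv"); P_ao <- chk(P_ao, "P_ao")
  P_nlv <- chk(P_nlv, "P_nlv"); P_nao <- chk(P_nao, "P_nao")
  if (is.null(P_nlv)) P_nlv <- P_lv
  if (is.null(P_nao)) P_nao <- P_ao
  if (!is.null(events)) {
    ev <- events
    req <- c("t_bs", "t_es", "t_close", "t_cycle_end")
    if (!all(req %in% names(ev))) {
      stop("events must contain ", paste(req, collapse = ", "))
    }
    with(ev, {
      if (!(t_bs < t_es && t_es <= t_close && t_close < t_cycle_end)) {
        stop("events must satisfy t_bs < t_es <= t_close < t_cycle_end")
      }
    })
    if (ev$t_bs < t[1] || ev$t_cycle_end > t[length(t)] + 1e-12) {
      stop("events must lie within the sampled time range")
    }
  }
  structure(list(t = t, Q = Q, P_lv = P_lv, P_ao = P_ao,
                 P_nlv = P_nlv, P_nao = P_nao, events = events),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples over [%.3g, %.3g] s%s\n",
              length(x$t), x$t[1], x$t[length(x$t)],
              if (is.null(x$events)) " (no events)" else ""))
  invisible(x)
}

#' Detect cycle events from the flow waveform
#'
#' Threshold-based detector: \code{t_bs}/\code{t_es} are the first upward
#' and last downward crossings of Q through +1 percent of its peak;
#' \code{t_close} is the first time after \code{t_es} where |Q| stays
#' within 1 percent of the peak for at least 10 ms; \code{t_cycle_end} is
#' the final sample.
#'
#' @param w \code{waveform}.
#' @param frac crossing threshold as a fraction of peak flow (default 0.01).
#' @param settle_s settling time for closure detection (default 0.01 s).
#' @return The waveform with its \code{events} field populated.
#' @export
detect_events <- function(w, frac = 0.01, settle_s = 0.01) {
  stopifnot(inherits(w, "waveform"))
  t <- w$t; Q <- w$Q
  thr <- frac * max(Q)
  if (max(Q) <= 0) stop("no forward flow; cannot detect events")
  above <- Q > thr
  i_bs <- which(above)[1]
  i_es <- which(above)[length(which(above))]
  # linear interpolation of the crossings
  interp_cross <- function(i0, i1) {
    if (i0 < 1 || Q[i1] == Q[i0]) return(t[i1])
    t[i0] + (thr - Q[i0]) * (t[i1] - t[i0]) / (Q[i1] - Q[i0])
  }
  t_bs <- if (i_bs > 1) interp_cross(i_bs - 1, i_bs) else t[1]
  t_es <- if (i_es < length(t)) interp_cross(i_es + 1, i_es) else t[length(t)]
  # closure: |Q| within threshold for >= settle_s after t_es
  t_close <- t[length(t)]
  quiet <- abs(Q) <= thr & t > t_es
  idx <- which(quiet)
  for (i in idx) {
    jend <- which(t >= t[i] + settle_s)
    if (length(jend) == 0) break
    j <- jend[1]
    if (all(quiet[i:j])) { t_close <- t[i]; break }
  }
  w$events <- list(t_bs = t_bs, t_es = t_es,
                   t_close = max(t_close, t_es),
                   t_cycle_end = t[length(t)])
  w
}

# trapezoidal integral of y(t) over [a, b], with linear interpolation of
# the integrand at the window endpoints
trapz_window <- function(t, y, a, b) {
  if (b <= a) return(0)
  ya <- stats::approx(t, y, xout = a, rule = 2)$y
  yb <- stats::approx(t, y, xout = b, rule = 2)$y
  inside <- t > a & t < b
  tt <- c(a, t[inside], b)
  yy <- c(ya, y[inside], yb)
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Forward, regurgitant and leakage volumes
#'
#' Trapezoidal quadrature of the clipped flow over the cycle phases:
#' forward volume \eqn{V_F = \int \max(Q, 0)\,dt} over systole
#' [t_bs, t_es]; regurgitant volume \eqn{V_R = \int \max(-Q, 0)\,dt} over
#' the closing phase [t_es, t_close]; leakage volume \eqn{V_L} likewise
#' over [t_close, t_cycle_end]. All reported as non-negative magnitudes.
#'
#' @param w \code{waveform} with events set.
#' @return List with V_F, V_R, V_L (mL), class \code{cycle_volumes}.
#' @export
cycle_volumes <- function(w) {
  stopifnot(inherits(w, "waveform"))
  ev <- w$events
  if (is.null(ev)) stop("waveform has no events; run detect_events() first")
  structure(list(
    V_F = trapz_window(w$t, pmax(w$Q, 0), ev$t_bs, ev$t_es),
    V_R = trapz_window(w$t, pmax(-w$Q, 0), ev$t_es, ev$t_close),
    V_L = trapz_window(w$t, pmax(-w$Q, 0), ev$t_close, ev$t_cycle_end)
  ), class = "cycle_volumes")
}

#' Regurgitant fraction
#'
#' \eqn{RF = (V_R + V_L)/V_F \times 100} percent.
#'
#' @param v \code{cycle_volumes} (or a list with V_F, V_R, V_L).
#' @return Percent.
#' @export
regurgitant_fraction <- function(v) {
  if (!is.finite(v$V_F) || v$V_F <= 0) {
    stop("regurgitant fraction undefined: forward volume is zero")
  }
  (v$V_R + v$V_L) / v$V_F * 100
}

#' Mean systolic transvalvular pressure gradient
#'
#' Time average of the near-valve pressure difference
#' \eqn{P_{nlv} - P_{nao}} over systole [t_bs, t_es], trapezoidal.
#'
#' @param w \code{waveform} with pressures and events.
#' @return mmHg.
#' @export
mean_tpg <- function(w) {
  stopifnot(inherits(w, "waveform"))
  ev <- w$events
  if (is.null(ev)) stop("waveform has no events")
  if (is.null(w$P_nlv) || is.null(w$P_nao)) {
    stop("waveform lacks near-valve pressures")
  }
  dur <- ev$t_es - ev$t_bs
  if (dur <= 0) stop("empty systolic window")
  trapz_window(w$t, w$P_nlv - w$P_nao, ev$t_bs, ev$t_es) / dur
}

#' Root-mean-square systolic flow
#'
#' \eqn{Q_{rms} = \sqrt{\int_{t_{bs}}^{t_{es}} Q^2 dt / (t_{es}-t_{bs})}}.
#'
#' @param w \code{waveform} with events.
#' @return mL/s.
#' @export
q_rms <- function(w) {
  stopifnot(inherits(w, "waveform"))
  ev <- w$events
  if (is.null(ev)) stop("waveform has no events")
  dur <- ev$t_es - ev$t_bs
  if (dur <= 0) stop("empty systolic window")
  sqrt(trapz_window(w$t, w$Q^2, ev$t_bs, ev$t_es) / dur)
}

#' Effective orifice area
#'
#' Gorlin-type continuity estimate
#' \eqn{EOA = Q_{rms} / (51.6\sqrt{\Delta P/\rho})} with Q in mL/s,
#' the mean systolic gradient \eqn{\Delta P} in mmHg and blood density
#' \eqn{\rho} in g/mL, giving cm^2.
#'
#' @param w \code{waveform} with events.
#' @param deltaP mean systolic gradient (mmHg); defaults to
#'   \code{mean_tpg(w)}.
#' @param rho blood density (g/mL), default 1.0.
#' @return cm^2.
#' @export
eoa <- function(w, deltaP = NULL, rho = 1.0) {
  stopifnot(inherits(w, "waveform"))
  if (is.null(deltaP)) deltaP <- mean_tpg(w)
  if (!is.finite(deltaP) || deltaP <= 0) {
    stop("EOA requires a positive mean pressure gradient")
  }
  q_rms(w) / (51.6 * sqrt(deltaP / rho))
}

# 1 mmHg * 1 mL in millijoule, to the precision conventionally used for
# the energy-loss index
MMHG_ML_TO_MJ <- 0.1333

#' Left-ventricular energy loss across the valve
#'
#' \eqn{E_L = 0.1333\int_{t_1}^{t_2} \Delta p(t) Q(t)\,dt} over one cardiac
#' cycle, with \eqn{\Delta p = P_{Ao} - P_{LV}} and the factor converting
#' mmHg mL to mJ. The signed integral is negative (the valve dissipates
#' ventricular work in every phase); by default the magnitude is returned,
#' matching the reporting convention for the index.
#'
#' @param w \code{waveform} with P_lv, P_ao and events.
#' @param signed if TRUE return the signed value.
#' @return mJ.
#' @export
energy_loss <- function(w, signed = FALSE) {
  stopifnot(inherits(w, "waveform"))
  if (is.null(w$P_lv) || is.null(w$P_ao)) {
    stop("waveform lacks inlet/outlet pressures")
  }
  ev <- w$events
  a <- w$t[1]
  b <- if (is.null(ev)) w$t[length(w$t)] else ev$t_cycle_end
  val <- MMHG_ML_TO_MJ * trapz_window(w$t, (w$P_ao - w$P_lv) * w$Q, a, b)
  if (signed) val else abs(val)
}

#' All four hemodynamic indices
#'
#' Convenience wrapper computing the regurgitant fraction, mean systolic
#' transvalvular gradient, effective orifice area and energy loss from one
#' waveform.
#'
#' @param w \code{waveform} with pressures and events.
#' @param rho blood density (g/mL).
#' @return List with RF_percent, TPG_mmHg, EOA_cm2, EL_mJ.
#' @export
hemodynamic_indices <- function(w, rho = 1.0) {
  v <- cycle_volumes(w)
  tpg <- mean_tpg(w)
  list(RF_percent = regurgitant_fraction(v),
       TPG_mmHg = tpg,
       EOA_cm2 = eoa(w, deltaP = tpg, rho = rho),
       EL_mJ = energy_loss(w))
}

#' Read a waveform from CSV (+ JSON events sidecar)
#'
#' CSV columns \code{t_s,Q_mL_per_s,Plv_mmHg,Pao_mmHg} and optionally
#' \code{Pnlv_mmHg,Pnao_mmHg}; events JSON holds t_bs, t_es, t_close,
#' t_cycle_end.
#'
#' @param path CSV file.
#' @param events_path optional JSON sidecar.
#' @return A \code{waveform}.
#' @export
read_waveform_csv <- function(path, events_path = NULL) {
  d <- utils::read.csv(path)
  ev <- if (!is.null(events_path)) jsonlite::fromJSON(events_path) else NULL
  waveform(d$t_s, d$Q_mL_per_s,
           P_lv = d$Plv_mmHg, P_ao = d$Pao_mmHg,
           P_nlv = d$Pnlv_mmHg, P_nao = d$Pnao_mmHg, events = ev)
}

#' Write a waveform to CSV (+ JSON events sidecar)
#'
#' @param w \code{waveform}.
#' @param path CSV file.
#' @param events_path optional JSON sidecar path.
#' @export
write_waveform_csv <- function(w, path, events_path = NULL) {
  stopifnot(inherits(w, "waveform"))
  d <- data.frame(t_s = w$t, Q_mL_per_s = w$Q)
  if (!is.null(w$P_lv)) d$Plv_mmHg <- w$P_lv
  if (!is.null(w$P_ao)) d$Pao_mmHg <- w$P_ao
  if (!is.null(w$P_nlv)) d$Pnlv_mmHg <- w$P_nlv
  if (!is.null(w$P_nao)) d$Pnao_mmHg <- w$P_nao
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  if (!is.null(events_path) && !is.null(w$events)) {
    writeLines(jsonlite::toJSON(w$events, auto_unbox = TRUE, digits = NA),
               events_path)
  }
  invisible(path)
}
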