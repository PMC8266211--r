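#' Three-element Windkessel parameters
#'
#' Lumped afterload model of the systemic circulation seen by the aortic
#' valve: characteristic resistance \code{Rc} in series with the parallel
#' combination of peripheral resistance \code{Rp} and arterial compliance
#' \code{C}. Defaults are the values used for a human "Type A" beat:
#' Rc = 0.033 mmHg s/mL, Rp = 0.79 mmHg s/mL, C = 1.75 mL/mmHg, initial
#' stored pressure 85 mmHg.
#'
#' @param Rc characteristic resistance (mmHg s/mL), > 0.
#' @param Rp peripheral resistance (mmHg s/mL), > 0.
#' @param C arterial compliance (mL/mmHg), > 0.
#' @param Pwk0 initial stored pressure (mmHg).
#' @return An object of class \code{windkessel_params}.
#' @export
windkessel_params <- function(Rc = 0.033, Rp = 0.79, C = 1.75, Pwk0 = 85) {
  stopifnot(Rc > 0, Rp > 0, C > 0, is.finite(Pwk0))
  structure(list(Rc = Rc, Rp = Rp, C = C, Pwk0 = Pwk0),
            class = "windkessel_params")
}

#' Advance the stored Windkessel pressure one step
#'
#' The stored pressure obeys \eqn{C\,dP_{Wk}/dt + P_{Wk}/R_p = Q}. For
#' piecewise-constant flow over the step the update is exact:
#' \deqn{P_{Wk}(t+\Delta t) = Q R_p + (P_{Wk}(t) - Q R_p)
#'       e^{-\Delta t/(R_p C)}.}
#'
#' @param params \code{windkessel_params}.
#' @param Pwk current stored pressure (mmHg).
#' @param Q flow into the aorta (mL/s), held constant over the step.
#' @param dt step (s), > 0.
#' @return Next stored pressure (mmHg).
#' @export
wk_step <- function(params, Pwk, Q, dt) {
  stopifnot(inherits(params, "windkessel_params"), dt > 0)
  qrp <- Q * params$Rp
  qrp + (Pwk - qrp) * exp(-dt / (params$Rp * params$C))
}

#' Aortic (outlet) pressure
#'
#' \eqn{P_{Ao} = Q R_c + P_{Wk}}.
#'
#' @param params \code{windkessel_params}.
#' @param Pwk stored pressure (mmHg).
#' @param Q flow (mL/s).
#' @return Outlet pressure (mmHg).
#' @export
wk_outlet_pressure <- function(params, Pwk, Q) {
  stopifnot(inherits(params, "windkessel_params"))
  Q * params$Rc + Pwk
}

#' Integrate the Windkessel over a flow history
#'
#' Stepwise exact-exponential integration: over each sampling interval the
#' flow is held at a constant effective value and the stored-pressure ODE
#' is advanced exactly, so the update itself is unconditionally stable and
#' free of integration error — only the flow sampling matters. With
#' \code{flow = "trapezoid"} (default) the effective value is the interval
#' average of the two endpoint samples, second-order accurate for smooth
#' flows; \code{flow = "left"} holds the left sample, reproducing a
#' left-hold piecewise-constant signal exactly. Output is on the input
#' grid.
#'
#' @param params \code{windkessel_params}.
#' @param t strictly increasing time samples (s).
#' @param Q flow samples (mL/s), same length as \code{t}.
#' @param flow per-interval flow convention, "trapezoid" or "left".
#' @return data.frame with columns t, Q, Pwk, Pao.
#' @export
wk_simulate <- function(params, t, Q, flow = c("trapezoid", "left")) {
  flow <- match.arg(flow)
  stopifnot(inherits(params, "windkessel_params"), length(t) == length(Q))
  if (length(t) == 0) {
    return(data.frame(t = numeric(0), Q = numeric(0),
                      Pwk = numeric(0), Pao = numeric(0)))
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("time grid must be strictly increasing")
  }
  n <- length(t)
  Pwk <- numeric(n)
  Pwk[1] <- params$Pwk0
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      qi <- if (flow == "left") Q[i] else (Q[i] + Q[i + 1]) / 2
      Pwk[i + 1] <- wk_step(params, Pwk[i], qi, t[i + 1] - t[i])
    }
  }
  data.frame(t = t, Q = Q, Pwk = Pwk,
             Pao = wk_outlet_pressure(params, Pwk, Q))
}

#' Read Windkessel parameters from JSON
#'
#' @param path JSON file with fields Rc, Rp, C and optionally Pwk0.
#' @return A \code{windkessel_params}.
#' @export
windkessel_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  windkessel_params(Rc = x$Rc, Rp = x$Rp, C = x$C,
                    Pwk0 = if (is.null(x$Pwk0)) 85 else x$Pwk0)
}
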