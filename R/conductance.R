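#' Ohmic ionic current
#'
#' A current of the form \code{gbar * prod(x_i^p_i) * (V - E_rev)} where the
#' \code{x_i} are gating variables. The current vanishes at the reversal
#' potential for any gate state.
#'
#' @param name current label.
#' @param gbar maximal conductance (mS/cm^2), non-negative.
#' @param E_rev reversal potential (mV).
#' @param gates named integer vector of gate exponents, e.g.
#'   \code{c(m = 3, h = 1)}; empty for a leak current.
#' @return an object of class \code{ohmic_current}.
#' @export
ohmic_current <- function(name, gbar, E_rev, gates = integer(0)) {
  if (gbar < 0) stop("gbar must be non-negative for current '", name, "'")
  structure(list(name = name, gbar = gbar, E_rev = E_rev, gates = gates),
            class = "ohmic_current")
}

#' Single-compartment membrane model
#'
#' Assembles a conductance-based model \code{C dV/dt = -sum(I_ionic) +
#' I_pump + I_app(t)} with first-order gate kinetics. The state vector is
#' the voltage followed by the dynamic gates in \code{gating} order.
#'
#' @param name model label.
#' @param capacitance membrane capacitance (uF/cm^2), positive.
#' @param currents list of \code{\link{ohmic_current}} objects.
#' @param gating named list of \code{\link{gate_kinetics}}, one per gate
#'   referenced by the currents.
#' @param pump_current constant DC current (uA/cm^2); hyperpolarizing
#'   calcium-pump currents are negative.
#' @param applied_current function of time (ms) returning uA/cm^2.
#' @return an object of class \code{membrane_model}.
#' @export
membrane_model <- function(name, capacitance, currents, gating,
                           pump_current = 0, applied_current = function(t) 0) {
  if (capacitance <= 0) stop("capacitance must be positive")
  need <- unique(unlist(lapply(currents, function(cc) names(cc$gates))))
  missing <- setdiff(need, names(gating))
  if (length(missing)) stop("missing gate kinetics: ",
                            paste(missing, collapse = ", "))
  dyn <- names(gating)[vapply(gating, function(g) g$mode == "dynamic",
                              logical(1))]
  structure(list(name = name, capacitance = capacitance, currents = currents,
                 gating = gating, pump_current = pump_current,
                 applied_current = applied_current, state_gates = dyn),
            class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat("<membrane_model>", x$name, "\n")
  cat("  C =", x$capacitance, "uF/cm^2;", length(x$currents), "currents;",
      "states: V,", paste(x$state_gates, collapse = ", "), "\n")
  for (cc in x$currents)
    cat(sprintf("  %-6s gbar = %6.3f mS/cm^2, E = %7.2f mV, gates: %s\n",
                cc$name, cc$gbar, cc$E_rev,
                if (length(cc$gates)) paste0(names(cc$gates), "^", cc$gates,
                                             collapse = " ") else "-"))
  invisible(x)
}

## gate values (named) given state vector and voltage
model_gate_values <- function(model, V, state) {
  vals <- numeric(0)
  for (g in model$gating) {
    vals[[g$name]] <- switch(g$mode,
      dynamic = state[[g$name]],
      instantaneous = g$inf(V),
      frozen = g$value)
  }
  vals
}

## total ionic current (uA/cm^2), excluding pump and applied current
model_ionic_current <- function(model, V, gate_values) {
  tot <- 0
  for (cc in model$currents) {
    open <- 1
    for (i in seq_along(cc$gates))
      open <- open * gate_values[[names(cc$gates)[i]]]^cc$gates[[i]]
    tot <- tot + cc$gbar * open * (V - cc$E_rev)
  }
  tot
}

## deSolve-style right-hand side
model_rhs <- function(model) {
  sg <- model$state_gates
  function(t, y, parms) {
    V <- y[1L]
    gv <- as.list(y[-1L])
    names(gv) <- sg
    vals <- model_gate_values(model, V, gv)
    dV <- (-model_ionic_current(model, V, vals) + model$pump_current +
             model$applied_current(t)) / model$capacitance
    dg <- vapply(sg, function(nm) gate_deriv(model$gating[[nm]], V, gv[[nm]]),
                 numeric(1))
    list(c(dV, dg))
  }
}

#' Canonical Hodgkin-Huxley model
#'
#' The four-state (V, m, h, n) squid-axon model with the original 1952 rate
#' functions and maximal conductances, in the shifted voltage convention
#' (rest near 0 mV, depolarization positive). The potassium Nernst
#' potential is -12 mV as in the original model; the sodium and leak Nernst
#' potentials are rounded to 120 mV and 10.6 mV.
#'
#' @param applied_current function of time (ms) returning uA/cm^2.
#' @return a \code{\link{membrane_model}}.
#' @export
build_hh <- function(applied_current = function(t) 0) {
  membrane_model(
    name = "hh",
    capacitance = 1,
    currents = list(
      ohmic_current("Na", 120, 120, c(m = 3, h = 1)),
      ohmic_current("K", 36, -12, c(n = 4)),
      ohmic_current("L", 0.3, 10.6)),
    gating = list(m = hh_gate("m"), h = hh_gate("h"), n = hh_gate("n")),
    applied_current = applied_current)
}

#' Hodgkin-Huxley model augmented with an L-type calcium current
#'
#' Adds a non-inactivating high-threshold calcium current
#' \code{g_ca * d * (V - E_Ca)} with activation kinetics on the potassium
#' timescale, plus a constant hyperpolarizing calcium-pump current. With
#' \code{g_ca = 0, i_pump = 0} the vector field is identical to
#' \code{\link{build_hh}}.
#'
#' @param g_ca maximal calcium conductance (mS/cm^2), non-negative.
#' @param i_pump constant pump current (uA/cm^2), typically negative.
#' @param E_ca calcium reversal potential (mV, shifted convention). The
#'   default places it well above the spike take-off region but below the
#'   sodium reversal, which yields the hyperpolarized rest / saddle /
#'   repulsive-branch equilibrium structure together with a spiking cycle
#'   that is born in a saddle-homoclinic bifurcation at a small positive
#'   current (so the burst collapses when a step is released).
#' @inheritParams build_hh
#' @return a \code{\link{membrane_model}}.
#' @export
build_hh_ca <- function(g_ca, i_pump, E_ca = 80,
                        applied_current = function(t) 0) {
  if (g_ca < 0) stop("g_ca must be non-negative")
  m <- build_hh(applied_current)
  m$name <- "hh_ca"
  m$currents <- c(m$currents, list(ohmic_current("Ca", g_ca, E_ca, c(d = 1))))
  m$gating$d <- ca_gate()
  m$pump_current <- i_pump
  m$state_gates <- c(m$state_gates, "d")
  m
}

## ---- Thalamocortical relay neuron (physiological convention, rest near
## -60/-75 mV). Sodium/potassium kinetics use the Traub-style rate
## functions with a threshold shift V_T; the T-type calcium current has a
## fast activation gate and a slow inactivation gate with the standard
## low-threshold window kinetics at 36 degC.
tc_VT <- -55

tc_alpha_m <- function(V) 0.32 * 4 * expm1_ratio(-(V - tc_VT - 13) / 4)
tc_beta_m  <- function(V) 0.28 * 5 * expm1_ratio((V - tc_VT - 40) / 5)
tc_alpha_h <- function(V) 0.128 * exp(-(V - tc_VT - 17) / 18)
tc_beta_h  <- function(V) 4 / (1 + exp(-(V - tc_VT - 40) / 5))
tc_alpha_n <- function(V) 0.032 * 5 * expm1_ratio(-(V - tc_VT - 15) / 5)
tc_beta_n  <- function(V) 0.5 * exp(-(V - tc_VT - 10) / 40)

tc_n_inf <- function(V) tc_alpha_n(V) / (tc_alpha_n(V) + tc_beta_n(V))
tc_m_inf <- function(V) tc_alpha_m(V) / (tc_alpha_m(V) + tc_beta_m(V))

tc_mT_inf <- function(V) 1 / (1 + exp(-(V + 57) / 6.2))
tc_mT_tau <- function(V)
  (0.612 + 1 / (exp(-(V + 131.6) / 16.7) + exp((V + 16.8) / 18.2))) / 3.737
tc_hT_inf <- function(V) 1 / (1 + exp((V + 81) / 4))
tc_hT_tau <- function(V)
  ifelse(V < -81, exp((V + 467) / 66.6), 28 + exp(-(V + 22) / 10.5)) / 3.737

#' Thalamocortical relay neuron model
#'
#' Single-compartment conductance-based model of a TC relay cell with fast
#' sodium and delayed-rectifier potassium currents, a low-threshold T-type
#' calcium current (fast activation \code{mT}, slow inactivation
#' \code{hT}), and ohmic plus potassium leak currents. State:
#' (V, m, h, n, mT, hT). Hyperpolarized holding deinactivates the T current
#' and switches the step response from tonic spiking to a delayed
#' plateau burst ending in an afterdepolarization.
#'
#' @inheritParams build_hh
#' @return a \code{\link{membrane_model}}.
#' @export
build_tc_complete <- function(applied_current = function(t) 0) {
  membrane_model(
    name = "tc_complete",
    capacitance = 1,
    currents = list(
      ohmic_current("Na", 90, 50, c(m = 3, h = 1)),
      ohmic_current("K", 10, -100, c(n = 4)),
      ohmic_current("T", 2, 120, c(mT = 2, hT = 1)),
      ohmic_current("L", 0.05, -70),
      ohmic_current("KL", 0.005, -100)),
    gating = list(
      m = gate_kinetics("m", tc_alpha_m, tc_beta_m),
      h = gate_kinetics("h", tc_alpha_h, tc_beta_h),
      n = gate_kinetics("n", tc_alpha_n, tc_beta_n),
      mT = gate_kinetics("mT", inf = tc_mT_inf, tau = tc_mT_tau),
      hT = gate_kinetics("hT", inf = tc_hT_inf, tau = tc_hT_tau)),
    applied_current = applied_current)
}

#' Steady state of a membrane model at constant current
#'
#' Roots of the steady-state current function \code{I_ss(V)} (all gates at
#' their voltage steady state) located by sign-change scanning plus
#' bisection, then assembled into full state vectors.
#'
#' @param model a \code{\link{membrane_model}}.
#' @param I_app constant applied current (uA/cm^2).
#' @param V_range voltage interval to scan (mV).
#' @param n_scan scan resolution.
#' @return a list of named state vectors (one per equilibrium voltage).
#' @export
resting_state <- function(model, I_app = 0, V_range = c(-120, 120),
                          n_scan = 2000) {
  iss <- function(V) {
    vapply(V, function(v) {
      vals <- lapply(model$gating, function(g)
        if (g$mode == "frozen") g$value else g$inf(v))
      names(vals) <- names(model$gating)
      -model_ionic_current(model, v, vals) + model$pump_current + I_app
    }, numeric(1))
  }
  Vg <- seq(V_range[1], V_range[2], length.out = n_scan)
  y <- iss(Vg)
  idx <- which(sign(y[-1]) * sign(y[-length(y)]) < 0)
  lapply(idx, function(i) {
    V <- uniroot(iss, c(Vg[i], Vg[i + 1]), tol = 1e-10)$root
    st <- c(V, vapply(model$state_gates,
                      function(nm) model$gating[[nm]]$inf(V), numeric(1)))
    names(st) <- c("v", model$state_gates)
    st
  })
}

#' Integrate a membrane model
#'
#' Stiff adaptive integration (lsoda) of the full conductance-based ODE
#' system. Gate values are bounded by the dynamics themselves; no hard
#' clipping is applied.
#'
#' @param model a \code{\link{membrane_model}}.
#' @param initial named state vector (\code{v} then dynamic gates);
#'   \code{NULL} uses the most hyperpolarized resting state at
#'   \code{applied_current(0)}.
#' @param t_max end time (ms).
#' @param dt output grid step (ms); internal steps are adaptive.
#' @param rtol,atol solver tolerances.
#' @param clamp_v if non-NULL, hold the voltage at this value (voltage
#'   clamp); gates still relax.
#' @return a \code{trace_recording} data frame with columns \code{t},
#'   \code{v}, one per dynamic gate, and \code{i_app}.
#' @export
simulate <- function(model, initial = NULL, t_max = 100, dt = 0.025,
                     rtol = 1e-8, atol = 1e-8, clamp_v = NULL) {
  if (is.null(initial)) {
    I0 <- model$applied_current(0)
    rs <- resting_state(model, I0)
    if (!length(rs)) stop("no resting state found for initial condition")
    initial <- rs[[1L]]
  }
  gates0 <- initial[-1L]
  if (any(gates0 < 0 | gates0 > 1))
    stop("initial gate values must lie in [0, 1]")
  rhs <- model_rhs(model)
  if (!is.null(clamp_v)) {
    base <- rhs
    rhs <- function(t, y, parms) {
      d <- base(t, c(clamp_v, y[-1L]), parms)[[1L]]
      d[1L] <- 0
      list(d)
    }
    initial[1L] <- clamp_v
  }
  times <- seq(0, t_max, by = dt)
  out <- deSolve::lsoda(y = unname(initial), times = times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 100000)
  if (nrow(out) < length(times))
    stop("solver failure at t = ", out[nrow(out), 1], " ms")
  if (any(!is.finite(out)))
    stop("non-finite state encountered during integration")
  df <- as.data.frame(out)
  names(df) <- c("t", "v", model$state_gates)
  df$i_app <- vapply(df$t, model$applied_current, numeric(1))
  class(df) <- c("trace_recording", "data.frame")
  attr(df, "model") <- model$name
  df
}

#' Step-current stimulation protocol
#'
#' @param holding holding current (uA/cm^2).
#' @param amplitude step amplitude added to the holding current.
#' @param onset,duration step onset time and duration (ms).
#' @return a function of time usable as \code{applied_current}, carrying
#'   its parameters as the \code{"protocol"} attribute.
#' @export
step_protocol <- function(holding = 0, amplitude = 0, onset = 0,
                          duration = Inf) {
  f <- function(t) holding + amplitude * (t >= onset & t < onset + duration)
  attr(f, "protocol") <- list(kind = "step", holding = holding,
                              amplitude = amplitude, onset = onset,
                              duration = duration)
  f
}

#' Superpose square pulses on an existing protocol
#'
#' @param base function of time (a protocol).
#' @param times pulse onset times (ms).
#' @param amplitude pulse amplitude (uA/cm^2).
#' @param width pulse width (ms).
#' @return a function of time; attribute \code{"protocol"} records the
#'   pulse train.
#' @export
pulse_protocol <- function(base, times, amplitude, width = 1) {
  f <- function(t) {
    p <- base(t)
    for (tp in times) p <- p + amplitude * (t >= tp & t < tp + width)
    p
  }
  attr(f, "protocol") <- c(attr(base, "protocol"),
                           list(pulses = list(times = times,
                                              amplitude = amplitude,
                                              width = width)))
  f
}
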