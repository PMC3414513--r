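#' Gating-variable kinetics
#'
#' A gate follows first-order kinetics \code{dx/dt = (x_inf(V) - x)/tau(V)},
#' specified either through forward/backward rate functions
#' \code{alpha(V), beta(V)} (1/ms) or directly through steady-state and
#' time-constant functions. \code{x_inf = alpha/(alpha+beta)} and
#' \code{tau = 1/(alpha+beta)} when rates are given.
#'
#' @param name gate label (e.g. "m", "h", "n", "d").
#' @param alpha,beta voltage-dependent rate functions (1/ms), or \code{NULL}.
#' @param inf,tau steady-state (dimensionless, in [0,1]) and time-constant
#'   (ms) functions; used when \code{alpha}/\code{beta} are \code{NULL}.
#' @param mode \code{"dynamic"} (integrated as a state variable),
#'   \code{"instantaneous"} (slaved to \code{inf(V)}) or \code{"frozen"}
#'   (held at \code{value}).
#' @param value frozen value when \code{mode = "frozen"}.
#' @return an object of class \code{gate_kinetics}.
#' @export
gate_kinetics <- function(name, alpha = NULL, beta = NULL, inf = NULL,
                          tau = NULL, mode = c("dynamic", "instantaneous",
                                               "frozen"), value = NA_real_) {
  mode <- match.arg(mode)
  if (is.null(inf)) {
    stopifnot(is.function(alpha), is.function(beta))
    inf <- function(V) { a <- alpha(V); a / (a + beta(V)) }
    tau <- function(V) 1 / (alpha(V) + beta(V))
  }
  structure(list(name = name, alpha = alpha, beta = beta, inf = inf,
                 tau = tau, mode = mode, value = value),
            class = "gate_kinetics")
}

#' @rdname gate_kinetics
#' @param gate a \code{gate_kinetics} object.
#' @param V membrane potential (mV); vectorized.
#' @export
gate_inf <- function(gate, V) gate$inf(V)

#' @rdname gate_kinetics
#' @export
gate_tau <- function(gate, V) gate$tau(V)

## time derivative of a gate value x at voltage V
gate_deriv <- function(gate, V, x) (gate$inf(V) - x) / gate$tau(V)

## ---- Hodgkin-Huxley rate functions (shifted convention, rest near 0 mV,
## depolarization positive; squid axon at 6.3 degC). The x/(exp(x)-1)
## singularities are removable and handled explicitly.
expm1_ratio <- function(x) ifelse(abs(x) < 1e-7, 1 - x / 2, x / (exp(x) - 1))

hh_alpha_m <- function(V) 0.1 * 10 * expm1_ratio((25 - V) / 10)
hh_beta_m  <- function(V) 4 * exp(-V / 18)
hh_alpha_h <- function(V) 0.07 * exp(-V / 20)
hh_beta_h  <- function(V) 1 / (exp((30 - V) / 10) + 1)
hh_alpha_n <- function(V) 0.01 * 10 * expm1_ratio((10 - V) / 10)
hh_beta_n  <- function(V) 0.125 * exp(-V / 80)

hh_m_inf <- function(V) hh_alpha_m(V) / (hh_alpha_m(V) + hh_beta_m(V))
hh_n_inf <- function(V) hh_alpha_n(V) / (hh_alpha_n(V) + hh_beta_n(V))
hh_h_inf <- function(V) hh_alpha_h(V) / (hh_alpha_h(V) + hh_beta_h(V))

hh_gate <- function(name) {
  switch(name,
         m = gate_kinetics("m", hh_alpha_m, hh_beta_m),
         h = gate_kinetics("h", hh_alpha_h, hh_beta_h),
         n = gate_kinetics("n", hh_alpha_n, hh_beta_n),
         stop("unknown HH gate: ", name))
}

## ---- L-type calcium activation. High-threshold, non-inactivating,
## activating on the potassium timescale: the steady state is tied to the
## potassium activation curve through the static burst-onset relation
## d = 1.5 n^3 (half-activation near V = +25 mV shifted, i.e. about -40 mV
## absolute) and the time constant is 1.5 tau_n, slightly slower than the
## recovery variable, so the calcium conductance outlasts each spike and
## sustains the plateau and the afterdepolarization.
ca_d_inf <- function(V) clip01(1.5 * hh_n_inf(V)^3)
ca_d_tau <- function(V) 1.5 / (hh_alpha_n(V) + hh_beta_n(V))

ca_gate <- function() gate_kinetics("d", inf = ca_d_inf, tau = ca_d_tau)
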