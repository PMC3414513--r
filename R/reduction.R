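#' Two-variable planar neuron model
#'
#' A slow-fast planar vector field \code{dV/dt = f(V, n, I)},
#' \code{dn/dt = eps * g(V, n)} on a physiological box, produced by
#' reducing a full conductance-based model. \code{eps} is an artificial
#' timescale-ratio knob used for singular-limit analysis: it rescales the
#' slow flow only, so nullclines and equilibria are eps-invariant
#' (\code{eps = 1} is the physical reduction).
#'
#' @param name model label.
#' @param f fast right-hand side, vectorized over \code{(V, n)}; signature
#'   \code{f(V, n, I, smooth = FALSE)}. With \code{smooth = TRUE} the
#'   static gate relations are evaluated without their [0,1] clipping
#'   (smooth extension used by singularity analysis).
#' @param g slow right-hand side (recovery kinetics), vectorized.
#' @param eps timescale ratio (dimensionless, >= 0).
#' @param box physiological box \code{c(V_min, V_max, n_min, n_max)}.
#' @param slow_tau function of V giving the recovery time constant (ms).
#' @param meta provenance list (source model, static relations used).
#' @param aux optional slow auxiliary gate kept dynamic only for
#'   simulation: list with \code{name}, \code{inf(V)}, \code{tau(V)},
#'   \code{frozen} (the value used by \code{f} in phase-plane analysis)
#'   and \code{f_aux(V, n, a, I)}.
#' @return an object of class \code{planar_model}.
#' @export
planar_model <- function(name, f, g, eps = 1,
                         box = c(-50, 120, 0, 1),
                         slow_tau = NULL, meta = list(), aux = NULL) {
  stopifnot(eps >= 0, is.function(f), is.function(g))
  structure(list(name = name, f = f, g = g, eps = eps, box = box,
                 slow_tau = slow_tau, meta = meta, aux = aux),
            class = "planar_model")
}

#' @export
print.planar_model <- function(x, ...) {
  cat("<planar_model>", x$name, " eps =", x$eps, "\n")
  cat("  box: V in [", x$box[1], ",", x$box[2], "] mV, n in [",
      x$box[3], ",", x$box[4], "]\n")
  if (!is.null(x$aux))
    cat("  frozen slow gate:", x$aux$name, "=", x$aux$frozen, "\n")
  invisible(x)
}

## linear + power-law static relations with optional clipping
static_linear <- function(a, b) function(x, smooth = FALSE) {
  y <- a + b * x
  if (smooth) y else clip01(y)
}
static_power <- function(c0, p) function(x, smooth = FALSE) {
  y <- c0 * sign(x) * abs(x)^p
  if (smooth) y else clip01(y)
}

#' Planar reduction of the (calcium-augmented) Hodgkin-Huxley model
#'
#' Classical FitzHugh-style reduction: sodium activation is instantaneous
#' (\code{m = m_inf(V)}), sodium inactivation follows the linear relation
#' \code{h = h0 - h1 * n}, and, when a calcium current is present, its
#' activation is slaved to the recovery variable through the static power
#' law \code{d = 1.5 n^3}. The recovery dynamics are the potassium
#' activation kinetics.
#'
#' @param model a \code{\link{membrane_model}} from \code{\link{build_hh}}
#'   or \code{\link{build_hh_ca}}.
#' @param eps timescale ratio for the slow variable (1 = physical).
#' @param h_relation linear coefficients \code{c(h0, h1)}; the default is
#'   the package fixture (least-squares fit over a spiking trajectory).
#' @param d_relation power-law coefficients \code{c(c, p)} for the calcium
#'   gate.
#' @return a \code{\link{planar_model}}.
#' @export
reduce_hh <- function(model, eps = 1,
                      h_relation = hourglass_fixture_constants$h_of_n,
                      d_relation = hourglass_fixture_constants$d_of_n) {
  cur <- setNames(model$currents,
                  vapply(model$currents, `[[`, "", "name"))
  if (!all(c("Na", "K", "L") %in% names(cur)))
    stop("model lacks the expected HH currents")
  gNa <- cur$Na$gbar; VNa <- cur$Na$E_rev
  gK <- cur$K$gbar; VK <- cur$K$E_rev
  gL <- cur$L$gbar; VL <- cur$L$E_rev
  has_ca <- "Ca" %in% names(cur) && cur$Ca$gbar > 0
  gCa <- if ("Ca" %in% names(cur)) cur$Ca$gbar else 0
  VCa <- if ("Ca" %in% names(cur)) cur$Ca$E_rev else 120
  pump <- model$pump_current
  C <- model$capacitance
  h_of_n <- static_linear(h_relation[1], h_relation[2])
  d_of_n <- static_power(d_relation[1], d_relation[2])
  f <- function(V, n, I = 0, smooth = FALSE) {
    iion <- gK * n^4 * (V - VK) +
      gNa * hh_m_inf(V)^3 * h_of_n(n, smooth) * (V - VNa) +
      gL * (V - VL) +
      gCa * d_of_n(n, smooth) * (V - VCa)
    (-iion + pump + I) / C
  }
  g <- function(V, n) hh_alpha_n(V) * (1 - n) - hh_beta_n(V) * n
  planar_model(
    name = if (has_ca) "reduced_hh_ca" else "reduced_hh",
    f = f, g = g, eps = eps,
    slow_tau = function(V) 1 / (hh_alpha_n(V) + hh_beta_n(V)),
    meta = list(source = model$name, g_ca = gCa, i_pump = pump,
                h_relation = h_relation,
                d_relation = if (has_ca) d_relation else NULL,
                merged = c("m -> m_inf(V)", "h -> h0 - h1*n",
                           if (has_ca) "d -> c*n^p")))
}

#' Planar reduction of the thalamocortical relay model
#'
#' Reduction with instantaneous sodium activation and the slow gates
#' merged into the potassium-activation recovery variable \code{n}:
#' sodium inactivation follows the linear relation \code{h = a + b n}
#' and T-type calcium activation the power law \code{mT = c n^p}, both
#' fitted over the burst window of the complete model (the power law is
#' fitted in log space so that the tiny activations of the
#' hyperpolarized resting state are respected). T-type inactivation
#' \code{hT}, whose timescale is much slower than every other gate, is
#' exposed as a frozen parameter of the planar model; for time-domain
#' simulation it can be kept dynamic (see \code{\link{simulate_planar}}
#' with \code{dynamic_aux = TRUE}).
#'
#' The analysis box is restricted to the subthreshold/plateau region
#' (V in [-100, -25] mV, n in [0, 0.75]) where the merged-gate relations
#' are meaningful.
#'
#' @param model a \code{\link{membrane_model}} from
#'   \code{\link{build_tc_complete}}.
#' @param h_T frozen T-type inactivation level in [0, 1]: near 0 in the
#'   depolarized (inactivated, tonic) mode, large when deinactivated by
#'   hyperpolarization (burst mode).
#' @param eps timescale ratio for the recovery variable.
#' @return a \code{\link{planar_model}} with an \code{aux} slot for
#'   \code{hT}.
#' @export
reduce_tc <- function(model, h_T = 0.05, eps = 1) {
  cur <- setNames(model$currents, vapply(model$currents, `[[`, "", "name"))
  if (!all(c("Na", "K", "T", "L", "KL") %in% names(cur)))
    stop("model lacks the expected TC currents")
  gNa <- cur$Na$gbar; VNa <- cur$Na$E_rev
  gK <- cur$K$gbar; VK <- cur$K$E_rev
  gT <- cur$T$gbar; VCa <- cur$T$E_rev
  gL <- cur$L$gbar; VL <- cur$L$E_rev
  gKL <- cur$KL$gbar; VKL <- cur$KL$E_rev
  C <- model$capacitance
  hr <- hourglass_fixture_constants$tc_h_of_n
  mr <- hourglass_fixture_constants$tc_mT_of_n
  h_of_n <- static_linear(hr[1], hr[2])
  mT_of_n <- static_power(mr[1], mr[2])
  f_aux <- function(V, n, a, I = 0, smooth = FALSE) {
    iion <- gK * n^4 * (V - VK) +
      gNa * tc_m_inf(V)^3 * h_of_n(n, smooth) * (V - VNa) +
      gT * mT_of_n(n, smooth)^2 * a * (V - VCa) +
      gL * (V - VL) + gKL * (V - VKL)
    (-iion + I) / C
  }
  f <- function(V, n, I = 0, smooth = FALSE) f_aux(V, n, h_T, I, smooth)
  g <- function(V, n) tc_alpha_n(V) * (1 - n) - tc_beta_n(V) * n
  planar_model(
    name = "reduced_tc",
    f = f, g = g, eps = eps,
    box = c(-100, -25, 0, 0.75),
    slow_tau = function(V) 1 / (tc_alpha_n(V) + tc_beta_n(V)),
    meta = list(source = model$name, h_relation = hr, mT_relation = mr,
                merged = c("m -> m_inf(V)", "h -> a + b*n",
                           "mT -> c*n^p", "hT frozen")),
    aux = list(name = "hT", inf = tc_hT_inf, tau = tc_hT_tau,
               frozen = h_T, f_aux = f_aux))
}

#' Holding-current adjustment for a reduced model
#'
#' Returns the constant current at which the reduced model's voltage
#' equation vanishes at a target resting potential (with the recovery
#' variable at its steady state), so that the reduced and complete
#' models share the resting potential under matched protocols.
#'
#' @param pm a \code{\link{planar_model}}.
#' @param v_rest target resting potential (mV).
#' @param n_rest recovery steady state at rest; default solves
#'   \code{g = 0} at \code{v_rest}.
#' @return holding current (uA/cm^2).
#' @export
holding_adjustment <- function(pm, v_rest, n_rest = NULL) {
  if (is.null(n_rest)) {
    n_rest <- tryCatch(
      uniroot(function(n) pm$g(v_rest, n), c(0, 1), tol = 1e-12)$root,
      error = function(e) stop("no recovery steady state at v_rest"))
  }
  -pm$f(v_rest, n_rest, 0)
}

#' Integrate a planar (reduced) model
#'
#' @param pm a \code{\link{planar_model}}.
#' @param initial named vector \code{c(v = , n = )} (plus the auxiliary
#'   gate when \code{dynamic_aux}); \code{NULL} starts from the most
#'   hyperpolarized equilibrium at \code{I(0)}.
#' @param t_max,dt time span and output step (ms).
#' @param I constant current or a protocol function of time.
#' @param dynamic_aux integrate the auxiliary slow gate (e.g. T-type
#'   inactivation) instead of freezing it.
#' @param rtol,atol solver tolerances.
#' @return a \code{trace_recording} data frame.
#' @export
simulate_planar <- function(pm, initial = NULL, t_max = 100, dt = 0.025,
                            I = 0, dynamic_aux = FALSE,
                            rtol = 1e-8, atol = 1e-8) {
  Ifun <- if (is.function(I)) I else function(t) I
  if (dynamic_aux && is.null(pm$aux))
    stop("model has no auxiliary slow gate")
  if (is.null(initial)) {
    eqs <- find_equilibria(pm, Ifun(0))
    if (!length(eqs)) stop("no equilibrium found for initial condition")
    loc <- eqs[[which.min(vapply(eqs, function(e) e$location[1],
                                 numeric(1)))]]$location
    initial <- c(v = loc[1], n = loc[2])
    if (dynamic_aux) initial <- c(initial, setNames(pm$aux$frozen,
                                                    pm$aux$name))
  }
  rhs <- if (dynamic_aux) {
    function(t, y, p) {
      list(c(pm$aux$f_aux(y[1], y[2], y[3], Ifun(t)),
             pm$eps * pm$g(y[1], y[2]),
             (pm$aux$inf(y[1]) - y[3]) / pm$aux$tau(y[1])))
    }
  } else {
    function(t, y, p) {
      list(c(pm$f(y[1], y[2], Ifun(t)), pm$eps * pm$g(y[1], y[2])))
    }
  }
  times <- seq(0, t_max, by = dt)
  out <- deSolve::lsoda(unname(initial), times, rhs, NULL,
                        rtol = rtol, atol = atol, maxsteps = 100000)
  if (nrow(out) < length(times))
    stop("solver failure at t = ", out[nrow(out), 1], " ms")
  df <- as.data.frame(out)
  names(df) <- c("t", "v", "n", if (dynamic_aux) pm$aux$name)
  df$i_app <- vapply(df$t, Ifun, numeric(1))
  class(df) <- c("trace_recording", "data.frame")
  attr(df, "model") <- pm$name
  df
}

#' Fit a static gate relation from a simulated trace
#'
#' Least-squares fit of one gating variable as a static function of
#' another over a trace window (typically burst initiation), supporting
#' the linear form \code{target = a + b * source} and the power law
#' \code{target = c * source^p}.
#'
#' @param trace a \code{trace_recording} containing both gate columns.
#' @param source_gate,target_gate column names.
#' @param form \code{"linear"} or \code{"power_law"}.
#' @param window optional time window \code{c(t0, t1)} restricting the fit.
#' @return list with \code{kind}, \code{coefficients}, \code{rms} and a
#'   \code{predict(x)} function (clipped to [0, 1]).
#' @export
fit_static_gate <- function(trace, source_gate, target_gate,
                            form = c("linear", "power_law"),
                            window = NULL) {
  form <- match.arg(form)
  stopifnot(all(c(source_gate, target_gate) %in% names(trace)))
  d <- as.data.frame(trace)
  if (!is.null(window)) d <- d[d$t >= window[1] & d$t <= window[2], ]
  x <- d[[source_gate]]; y <- d[[target_gate]]
  if (max(x) - min(x) < 1e-6) stop("degenerate trace: source gate constant")
  if (form == "linear") {
    fit <- lm(y ~ x)
    cf <- unname(coef(fit))
    coefficients <- c(a = cf[1], b = cf[2])
    pred <- function(z) clip01(cf[1] + cf[2] * z)
  } else {
    keep <- x > 1e-6 & y > 1e-8
    if (sum(keep) < 10) stop("degenerate trace for power-law fit")
    init <- coef(lm(log(y[keep]) ~ log(x[keep])))
    st <- list(c0 = exp(unname(init[1])), p = unname(init[2]))
    ## an exact power law makes the zero-residual nls fit grumble;
    ## the log-log start is then already the answer
    fit <- tryCatch(
      suppressWarnings(
        nls(y ~ c0 * x^p, data = data.frame(x = x[keep], y = y[keep]),
            start = st, control = list(maxiter = 200, warnOnly = TRUE))),
      error = function(e) NULL)
    cf <- if (is.null(fit)) unlist(st) else coef(fit)
    coefficients <- c(c = unname(cf[1]), p = unname(cf[2]))
    pred <- function(z) clip01(unname(cf[1]) * z^unname(cf[2]))
  }
  rms <- sqrt(mean((pred(x) - clip01(y))^2))
  list(kind = form, coefficients = coefficients, rms = rms, predict = pred)
}

#' Total ionic current versus the recovery variable at fixed voltage
#'
#' Profiles \code{I_total(n)} at fixed \code{V} for a planar model, where
#' \code{I_total} includes the constant pump current as a vertical shift
#' (so the voltage nullcline solves \code{I_total = I_app}). Also counts
#' the sign changes of \code{dI_total/dn} on the grid: zero sign changes
#' (monotone increase) permit at most one nullcline branch, a single sign
#' change (decreasing then increasing, the calcium signature) permits two.
#'
#' @param pm a \code{\link{planar_model}}.
#' @param V fixed membrane potential (mV).
#' @param n_grid mesh over [0, 1].
#' @return list with a data frame \code{profile} (n, i_total) and
#'   \code{sign_changes}.
#' @export
ionic_current_profile <- function(pm, V, n_grid = seq(0, 1,
                                                      length.out = 1000)) {
  stopifnot(all(n_grid >= 0 & n_grid <= 1))
  itot <- -pm$f(V, n_grid, 0)      # C = 1 uF/cm^2 in all package models
  dI <- diff(itot) / diff(n_grid)
  s <- sign(dI)
  s <- s[s != 0]
  sc <- sum(diff(s) != 0)
  list(profile = data.frame(n = n_grid, i_total = itot),
       sign_changes = sc)
}
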