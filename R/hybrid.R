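#' Hybrid (integrate-and-reset) neuron models
#'
#' Continuous subthreshold dynamics in (v, w) or (v, w, z) with a spike
#' threshold and a reset map. Two families are provided:
#' \describe{
#'   \item{transcritical}{fast equation \code{dv/dt = v^2 - k w^2 + I - z}
#'     whose nullcline is an X (two crossing lines) near the origin: the
#'     local normal form of a transcritical singularity. The recovery
#'     nullcline offset \code{w0} is the image of the calcium
#'     conductance: \code{w0 > 0} places the rest point above the
#'     singularity (low calcium, tonic), \code{w0 < 0} below it (high
#'     calcium: latency, plateau burst, ADP).}
#'   \item{fold}{fast equation \code{dv/dt = v^2 - w + I - z}
#'     (Izhikevich-style quadratic with a parabolic nullcline), the
#'     classical fold normal form, used as the comparison baseline.}
#' }
#' The slow adaptation \code{z} (image of intracellular calcium and the
#' pump current it activates) relaxes linearly (\code{dz/dt = -eps_z z})
#' and receives a fixed increment at each spike; it can be disabled by
#' setting its increment and initial value to zero.
#'
#' @param variant \code{"transcritical"} or \code{"fold"}.
#' @param params named list overriding the variant defaults; see
#'   \code{\link{hybrid_defaults}}.
#' @param applied_current function of time, or a constant.
#' @return an object of class \code{hybrid_model}.
#' @export
hybrid_model <- function(variant = c("transcritical", "fold"),
                         params = list(),
                         applied_current = function(t) 0) {
  variant <- match.arg(variant)
  p <- modifyList(hybrid_defaults(variant), params)
  stopifnot(p$eps > 0, p$v_reset < p$v_threshold)
  Ifun <- if (is.function(applied_current)) applied_current
          else function(t) applied_current
  f <- if (variant == "transcritical")
    function(v, w, z, I) v^2 - p$k * w^2 + I - z
  else
    function(v, w, z, I) v^2 - w + I - z
  structure(list(variant = variant, params = p, f = f,
                 applied_current = Ifun),
            class = "hybrid_model")
}

#' Default hybrid-model parameters
#'
#' Canonical coefficient sets (dimensionless units). Shared structure:
#' \code{dv/dt} as in \code{\link{hybrid_model}},
#' \code{dw/dt = eps (a v - w + w0)}, \code{dz/dt = -eps_z z}; reset
#' \code{v -> v_reset, w -> w + d_w, z -> z + d_z} at
#' \code{v = v_threshold}.
#'
#' @param variant model family.
#' @return named list of parameters.
#' @export
hybrid_defaults <- function(variant = c("transcritical", "fold")) {
  variant <- match.arg(variant)
  if (variant == "transcritical")
    list(k = 1, a = 0.25, eps = 0.05, w0 = 0.2,
         eps_z = 0.002, d_z = 0.01,
         v_threshold = 2, v_reset = -0.1, d_w = 0.2,
         I_off = -0.5, I_on = 0.0625)
  else
    list(a = 0.25, eps = 0.3, w0 = -0.05,
         eps_z = 0.001, d_z = 0.0605,
         v_threshold = 2, v_reset = -0.2, d_w = -0.3,
         I_off = -0.5, I_on = 0.0625)
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat("<hybrid_model>", x$variant, "\n")
  p <- x$params
  cat(sprintf("  eps = %g, w0 = %g, reset: v -> %g, w -> w + %g, z -> z + %g\n",
              p$eps, p$w0, p$v_reset, p$d_w, p$d_z))
  invisible(x)
}

#' Transcritical hybrid model
#'
#' @param w0 recovery-nullcline offset (sign selects the calcium mode).
#' @param params further overrides.
#' @param applied_current protocol function or constant.
#' @return a \code{\link{hybrid_model}}.
#' @export
build_transcritical <- function(w0 = 0.2, params = list(),
                                applied_current = function(t) 0) {
  ## plain two-variable model: the slow adaptation is off unless the
  ## caller turns it on
  hybrid_model("transcritical",
               modifyList(list(w0 = w0, d_z = 0), params),
               applied_current)
}

#' Fold (Izhikevich-style) hybrid model
#'
#' @inheritParams build_transcritical
#' @return a \code{\link{hybrid_model}}.
#' @export
build_fold <- function(params = list(),
                       applied_current = function(t) 0) {
  hybrid_model("fold", params, applied_current)
}

#' Thalamocortical hybrid model in a calcium-conductance mode
#'
#' Three-variable transcritical hybrid model of a TC relay cell with the
#' slow adaptation variable active. The two modes differ ONLY in the
#' sign of \code{w0} (the image of the amount of deinactivated T-type
#' calcium conductance): \code{low_ca} responds to a step with a slow
#' regular spike train, \code{high_ca} with a delayed plateau burst
#' ending in an afterdepolarization, from a more hyperpolarized rest.
#'
#' @param mode \code{"low_ca"} or \code{"high_ca"}.
#' @param step_onset,step_duration stimulation window (time units); the
#'   injected current is \code{I_off} outside it and \code{I_on} inside.
#' @param params further overrides (applied after the mode's \code{w0}).
#' @return a \code{\link{hybrid_model}}.
#' @export
build_tc_hybrid <- function(mode = c("low_ca", "high_ca"),
                            step_onset = 100, step_duration = 400,
                            params = list()) {
  mode <- match.arg(mode)
  base <- hybrid_defaults("transcritical")
  w0 <- if (mode == "low_ca") abs(base$w0) else -abs(base$w0)
  p <- modifyList(list(w0 = w0), params)
  tmp <- modifyList(base, p)
  prot <- step_protocol(tmp$I_off, tmp$I_on - tmp$I_off, step_onset,
                        step_duration)
  m <- hybrid_model("transcritical", p, prot)
  m$mode <- mode
  m
}

#' Integrate a hybrid model with event detection
#'
#' Adaptive integration of the continuous dynamics with root finding on
#' \code{v - v_threshold}; at each event the reset map is applied and
#' integration restarts. Guards against Zeno behavior by aborting after
#' \code{max_events} resets.
#'
#' @param hm a \code{\link{hybrid_model}}.
#' @param initial named state \code{c(v=, w=)} or \code{c(v=, w=, z=)};
#'   \code{NULL} starts from the subthreshold equilibrium at
#'   \code{applied_current(0)} (with \code{z = 0}).
#' @param t_max,dt horizon and output step.
#' @param rtol,atol solver tolerances.
#' @param max_events Zeno guard.
#' @return a data frame of class \code{hybrid_trace} with columns
#'   \code{t, v, w, z, i_app}; spike (reset) times in attribute
#'   \code{"spike_times"}.
#' @export
simulate_hybrid <- function(hm, initial = NULL, t_max = 500, dt = 0.1,
                            rtol = 1e-10, atol = 1e-10,
                            max_events = 1e6) {
  p <- hm$params
  if (is.null(initial)) {
    eq <- hybrid_rest(hm, hm$applied_current(0))
    initial <- c(v = eq[1], w = eq[2], z = 0)
  }
  if (length(initial) == 2) initial <- c(initial, z = 0)
  if (initial[1] >= p$v_threshold)
    stop("initial v must be below the spike threshold")
  rhs <- function(t, y, parms) {
    I <- hm$applied_current(t)
    list(c(hm$f(y[1], y[2], y[3], I),
           p$eps * (p$a * y[1] - y[2] + p$w0),
           -p$eps_z * y[3]))
  }
  rootfun <- function(t, y, parms) y[1] - p$v_threshold
  times_all <- seq(0, t_max, by = dt)
  out_rows <- list(); spikes <- numeric(0)
  t0 <- 0; y <- unname(initial); n_ev <- 0
  while (t0 < t_max) {
    times <- c(t0, times_all[times_all > t0 + 1e-12])
    if (length(times) < 2) break
    seg <- suppressWarnings(
      deSolve::lsodar(y, times, rhs, NULL, rtol = rtol, atol = atol,
                      rootfunc = rootfun, maxsteps = 100000))
    troot <- attr(seg, "troot")
    out_rows[[length(out_rows) + 1]] <- seg[-1, , drop = FALSE]
    if (!is.null(troot) && length(troot)) {
      n_ev <- n_ev + 1
      if (n_ev > max_events)
        stop("Zeno guard: more than ", max_events, " reset events ",
             "(last at t = ", troot, ")")
      spikes <- c(spikes, troot[1])
      yl <- seg[nrow(seg), -1]
      y <- c(p$v_reset, yl[2] + p$d_w, yl[3] + p$d_z)
      t0 <- troot[1]
    } else {
      t0 <- t_max
    }
  }
  out <- do.call(rbind, out_rows)
  df <- data.frame(t = out[, 1], v = out[, 2], w = out[, 3], z = out[, 4])
  df <- df[!duplicated(df$t), ]
  df$i_app <- vapply(df$t, hm$applied_current, numeric(1))
  class(df) <- c("hybrid_trace", "trace_recording", "data.frame")
  attr(df, "spike_times") <- spikes
  attr(df, "model") <- hm$variant
  df
}

## subthreshold equilibrium of the continuous dynamics (z = 0):
## intersection of the w-nullcline with the attracting part of the
## v-nullcline, found by scanning v
hybrid_rest <- function(hm, I) {
  p <- hm$params
  vf <- function(v) hm$f(v, p$a * v + p$w0, 0, I)
  vg <- seq(-6, p$v_threshold, length.out = 4000)
  y <- vf(vg)
  idx <- which(diff(sign(y)) != 0)
  if (!length(idx)) stop("no subthreshold equilibrium at I = ", I)
  roots <- vapply(idx, function(i)
    uniroot(vf, c(vg[i], vg[i + 1]), tol = 1e-12)$root, numeric(1))
  ## attracting requires dv'/dv < 0 along the nullcline and stable slow
  ## dynamics; take the most hyperpolarized root with negative slope
  slope <- (vf(roots + 1e-6) - vf(roots - 1e-6)) / 2e-6
  ok <- roots[slope < 0]
  v <- if (length(ok)) min(ok) else min(roots)
  c(v, p$a * v + p$w0)
}

#' Spike-time robustness to small current pulses
#'
#' Reruns a hybrid simulation with small square current pulses
#' superposed on the protocol and reports the change in total spike
#' count plus a per-pulse classification (\code{"absorbed"} when no
#' additional spike follows within \code{window} after the pulse,
#' \code{"extra_spike"} otherwise).
#'
#' @param hm a \code{\link{hybrid_model}}.
#' @param pulse_times pulse onsets.
#' @param amplitude,width pulse amplitude and width.
#' @param t_max simulation horizon.
#' @param initial initial state passed to \code{\link{simulate_hybrid}}.
#' @param window per-pulse attribution window.
#' @return list with \code{extra_spikes} (count difference),
#'   \code{per_pulse} (character vector), \code{nominal_spikes},
#'   \code{pulsed_spikes}.
#' @export
pulse_robustness <- function(hm, pulse_times, amplitude, width = 2,
                             t_max = 500, initial = NULL, window = 30) {
  nom <- simulate_hybrid(hm, initial = initial, t_max = t_max)
  hp <- hm
  hp$applied_current <- pulse_protocol(hm$applied_current, pulse_times,
                                       amplitude, width)
  per <- simulate_hybrid(hp, initial = initial, t_max = t_max)
  s0 <- attr(nom, "spike_times"); s1 <- attr(per, "spike_times")
  per_pulse <- vapply(pulse_times, function(tp) {
    n0 <- sum(s0 >= tp & s0 < tp + window)
    n1 <- sum(s1 >= tp & s1 < tp + window)
    if (n1 > n0) "extra_spike" else "absorbed"
  }, character(1))
  list(extra_spikes = length(s1) - length(s0), per_pulse = per_pulse,
       nominal_spikes = s0, pulsed_spikes = s1)
}
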