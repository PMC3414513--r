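## Trace-level detection of the triple electrophysiological signature of
## high calcium conductance: spike latency, plateau oscillations, and the
## afterdepolarization (ADP), plus response classification.

trace_cols <- function(trace) {
  stopifnot(all(c("t", "v") %in% names(trace)))
  as.data.frame(trace)[, intersect(c("t", "v", "i_app"), names(trace))]
}

## onset/offset of the stimulation step from the applied-current column
detect_step_window <- function(trace) {
  if (!"i_app" %in% names(trace)) return(c(NA_real_, NA_real_))
  d <- which(diff(trace$i_app) != 0)
  if (!length(d)) return(c(NA_real_, NA_real_))
  c(trace$t[d[1] + 1], trace$t[d[length(d)] + 1])
}

#' Resting membrane potential of a trace
#'
#' Median voltage before the stimulus onset (robust to onset
#' transients); falls back to the median of the first tenth of the trace
#' when no stimulus step is present.
#'
#' @param trace a \code{trace_recording}.
#' @param step_onset stimulus onset; \code{NULL} reads it from the
#'   \code{i_app} column.
#' @return resting voltage (mV or model units).
#' @export
resting_voltage <- function(trace, step_onset = NULL) {
  d <- trace_cols(trace)
  if (is.null(step_onset)) step_onset <- detect_step_window(trace)[1]
  pre <- if (is.finite(step_onset)) d$v[d$t < step_onset] else numeric(0)
  if (length(pre) < 5) pre <- d$v[seq_len(max(5, nrow(d) %/% 10))]
  median(pre)
}

#' Spike detection by threshold crossing
#'
#' Upward crossings of a voltage threshold separated by at least the
#' refractory interval. For hybrid (reset) traces the recorded reset
#' events are used directly.
#'
#' @param trace a \code{trace_recording} or \code{hybrid_trace}.
#' @param threshold crossing level; default is midway between rest and
#'   the trace maximum.
#' @param refractory minimum spike separation (time units).
#' @return numeric vector of spike times.
#' @export
detect_spikes <- function(trace, threshold = NULL, refractory = 2) {
  st <- attr(trace, "spike_times")
  if (!is.null(st)) return(st)
  d <- trace_cols(trace)
  if (!nrow(d)) stop("empty trace")
  if (is.null(threshold)) {
    rv <- resting_voltage(trace)
    threshold <- rv + 0.5 * (max(d$v) - rv)
    if (max(d$v) - rv < 1e-9) return(numeric(0))
  }
  upcross_times(d$t, d$v, threshold, min_sep = refractory)
}

#' Spike latency relative to stimulus onset
#'
#' @param trace a trace.
#' @param step_onset stimulus onset time; \code{NULL} reads it from
#'   \code{i_app}.
#' @param ... passed to \code{\link{detect_spikes}}.
#' @return latency (first spike time minus onset) or \code{NA} if the
#'   trace has no spike.
#' @export
measure_latency <- function(trace, step_onset = NULL, ...) {
  if (is.null(step_onset)) step_onset <- detect_step_window(trace)[1]
  stopifnot(is.finite(step_onset))
  st <- detect_spikes(trace, ...)
  st <- st[st >= step_onset]
  if (!length(st)) return(NA_real_)
  st[1] - step_onset
}

#' Plateau-oscillation detection
#'
#' The plateau floor is the minimum voltage between the first and last
#' spike of the burst; plateau oscillations are flagged when the floor
#' stays depolarized relative to the resting potential by more than
#' \code{margin_frac} of the spike amplitude (trace peak minus rest).
#'
#' @param trace a trace.
#' @param spike_times spike times (default: detected).
#' @param resting_v resting potential (default: pre-stimulus median).
#' @param margin_frac depolarization margin as a fraction of the spike
#'   amplitude.
#' @return list with \code{plateau} flag, \code{floor}, \code{margin}.
#' @export
detect_plateau <- function(trace, spike_times = NULL, resting_v = NULL,
                           margin_frac = 0.18) {
  d <- trace_cols(trace)
  if (is.null(spike_times)) spike_times <- detect_spikes(trace)
  if (length(spike_times) < 2)
    stop("plateau detection needs at least two spikes")
  if (is.null(resting_v)) resting_v <- resting_voltage(trace)
  seg <- d$v[d$t > spike_times[1] & d$t < spike_times[length(spike_times)]]
  floor_v <- min(seg)
  amp <- max(d$v) - resting_v
  margin <- margin_frac * amp
  list(plateau = floor_v > resting_v + margin, floor = floor_v,
       margin = margin)
}

#' Afterdepolarization detection
#'
#' Searches the post-burst segment (after the last spike) for a local
#' voltage maximum that follows an initial repolarization and precedes
#' the final settling: the trace must first descend to a local minimum,
#' then rise to an apex below the spike range, then settle. Candidate
#' apexes that coincide with a discontinuity of the applied current are
#' ignored (a stimulus edge is not an ADP). The apex amplitude is
#' measured relative to the final rest level (median over the trailing
#' \code{settle_window}); the flag requires at least \code{min_frac} of
#' the spike amplitude.
#'
#' @param trace a trace.
#' @param spike_times spike times (default: detected).
#' @param settle_window trailing window over which the final rest level
#'   is measured; default one tenth of the post-burst duration.
#' @param min_frac minimum apex amplitude as a fraction of the spike
#'   amplitude.
#' @param resting_v resting potential (for the spike-amplitude scale).
#' @param blank dead time after the last spike excluded from the search
#'   (covers the spike's own peak and downstroke).
#' @return list with \code{adp} flag, \code{apex_time},
#'   \code{apex_voltage}, \code{amplitude}, \code{final_rest}.
#' @export
detect_adp <- function(trace, spike_times = NULL, settle_window = NULL,
                       min_frac = 0.05, resting_v = NULL, blank = 2) {
  d <- trace_cols(trace)
  if (is.null(spike_times)) spike_times <- detect_spikes(trace)
  if (!length(spike_times)) stop("ADP detection needs at least one spike")
  if (is.null(resting_v)) resting_v <- resting_voltage(trace)
  t_last <- spike_times[length(spike_times)]
  ## blank the last spike's own peak and downstroke
  post <- d[d$t > t_last + blank, , drop = FALSE]
  if (nrow(post) < 20)
    stop("insufficient post-spike data for ADP detection")
  if (is.null(settle_window))
    settle_window <- 0.1 * (max(post$t) - min(post$t))
  final_rest <- median(post$v[post$t > max(post$t) - settle_window])
  amp <- max(d$v) - resting_v
  none <- list(adp = FALSE, apex_time = NA_real_,
               apex_voltage = NA_real_, amplitude = NA_real_,
               final_rest = final_rest)
  ## skip the spike downstroke: start at the first sample below the
  ## upper half of the spike range
  dn <- which(post$v < resting_v + 0.6 * amp)
  if (!length(dn)) return(none)
  ## for reset (hybrid) traces the downstroke is the reset discontinuity
  ## itself, so the segment may already start repolarized
  seg <- post[dn[1]:nrow(post), , drop = FALSE]
  imax <- local_maxima(seg$v)
  if (!length(imax)) return(none)
  ## drop maxima at stimulus discontinuities
  if ("i_app" %in% names(seg)) {
    edges <- which(abs(diff(seg$i_app)) > 0)
    bad <- unique(unlist(lapply(edges, function(e)
      seq(max(1, e - 3), min(nrow(seg), e + 3)))))
    imax <- setdiff(imax, bad)
  }
  ## apex below the spike range
  imax <- imax[seg$v[imax] < resting_v + 0.8 * amp]
  if (!length(imax)) return(none)
  i <- imax[which.max(seg$v[imax])]
  apex_amp <- seg$v[i] - final_rest
  list(adp = apex_amp >= min_frac * amp, apex_time = seg$t[i],
       apex_voltage = seg$v[i], amplitude = apex_amp,
       final_rest = final_rest)
}

#' Full signature report for a step-response trace
#'
#' Runs spike, latency, plateau and ADP detection and classifies the
#' response as \code{"silent"}, \code{"tonic"}, \code{"burst"} (plateau
#' without the full signature) or \code{"burst_with_signature"}
#' (latency present, plateau oscillations, and an ADP).
#'
#' @param trace a trace with an \code{i_app} column (or explicit
#'   \code{step_onset}).
#' @param step_onset stimulus onset (default: from \code{i_app}).
#' @param threshold spike threshold (default: midway rest-to-peak).
#' @param refractory minimum spike separation.
#' @param margin_frac plateau margin fraction.
#' @param adp_min_frac minimum ADP amplitude fraction.
#' @param settle_window see \code{\link{detect_adp}}.
#' @return list of class \code{signature_report}.
#' @export
signature_report <- function(trace, step_onset = NULL, threshold = NULL,
                             refractory = 2, margin_frac = 0.18,
                             adp_min_frac = 0.05, settle_window = NULL) {
  if (is.null(step_onset)) step_onset <- detect_step_window(trace)[1]
  rv <- resting_voltage(trace, step_onset)
  st <- detect_spikes(trace, threshold, refractory)
  lat <- if (length(st) && is.finite(step_onset))
    max(st[1] - step_onset, 0) else NA_real_
  pl <- if (length(st) >= 2)
    detect_plateau(trace, st, rv, margin_frac)
  else list(plateau = FALSE, floor = NA_real_)
  adp <- if (length(st) >= 1)
    tryCatch(detect_adp(trace, st, settle_window, adp_min_frac, rv),
             error = function(e) list(adp = FALSE, apex_time = NA_real_,
                                      amplitude = NA_real_))
  else list(adp = FALSE, apex_time = NA_real_, amplitude = NA_real_)
  classification <- if (!length(st)) "silent"
  else if (pl$plateau && adp$adp && is.finite(lat)) "burst_with_signature"
  else if (pl$plateau) "burst"
  else "tonic"
  structure(list(spike_times = st, latency = lat,
                 plateau = pl$plateau, plateau_floor = pl$floor,
                 adp = adp$adp, adp_apex_time = adp$apex_time,
                 adp_amplitude = adp$amplitude, resting_v = rv,
                 classification = classification),
            class = "signature_report")
}

#' @export
print.signature_report <- function(x, ...) {
  cat("<signature_report>", x$classification, "\n")
  cat(sprintf("  %d spikes; latency %s; plateau %s (floor %s); ADP %s\n",
              length(x$spike_times),
              if (is.finite(x$latency)) sprintf("%.2f", x$latency)
              else "absent",
              x$plateau,
              if (is.finite(x$plateau_floor))
                sprintf("%.2f", x$plateau_floor) else "-",
              x$adp))
  invisible(x)
}
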