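## Shared, lazily computed fixtures. Heavy simulations are run once per
## test session and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## canonical step protocol of the conductance fixtures
fig_step <- function() step_protocol(0, 10, 20, 60)

trace_hh <- function() cached("trace_hh", {
  simulate(build_hh(fig_step()), t_max = 250)
})

trace_hh_ca <- function() cached("trace_hh_ca", {
  simulate(get_fixture("hh_ca"), t_max = 250)
})

reduced_hh <- function() cached("reduced_hh", reduce_hh(build_hh()))

reduced_hh_ca <- function() cached("reduced_hh_ca", {
  reduce_hh(build_hh_ca(3, -15.6))
})

trace_hybrid_high <- function() cached("trace_hybrid_high", {
  simulate_hybrid(build_tc_hybrid("high_ca", 100, 400), t_max = 700)
})

trace_hybrid_low <- function() cached("trace_hybrid_low", {
  simulate_hybrid(build_tc_hybrid("low_ca", 100, 400), t_max = 700)
})

## TC protocols: holding currents of the two modes, step +0.8 uA/cm^2
tc_protocol <- function(mode, duration = 200) {
  holding <- if (mode == "tonic") 0.2 else -0.6
  step_protocol(holding, 0.8, 50, duration)
}

trace_tc_burst <- function() cached("trace_tc_burst", {
  simulate(build_tc_complete(tc_protocol("burst")), t_max = 300)
})

trace_tc_tonic <- function() cached("trace_tc_tonic", {
  simulate(build_tc_complete(tc_protocol("tonic")), t_max = 300)
})

## simple analytic planar test systems
toy_linear <- function() {
  planar_model("toy_linear",
               f = function(V, n, I = 0, smooth = FALSE) -V + n + I,
               g = function(V, n) -V - n,
               box = c(-1, 1, -1, 1))
}

toy_transcritical <- function() {
  planar_model("toy_tc",
               f = function(V, n, I = 0, smooth = FALSE) V^2 - n^2 + I,
               g = function(V, n) 0.3 * V - n,
               box = c(-1, 1, -1, 1))
}

toy_fold <- function() {
  planar_model("toy_fold",
               f = function(V, n, I = 0, smooth = FALSE) V^2 + n + I,
               g = function(V, n) -n - 0.5,
               box = c(-1, 1, -1, 1))
}

## spike counter on a plain voltage trace
count_spikes <- function(tr, threshold, window = NULL, min_sep = 2) {
  st <- hourglass:::upcross_times(tr$t, tr$v, threshold, min_sep = min_sep)
  if (!is.null(window)) st <- st[st >= window[1] & st < window[2]]
  length(st)
}
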