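# hourglass

Dynamical-systems tooling for neuronal excitability shaped by slow
calcium currents: conductance-based models, planar reductions,
phase-plane and bifurcation analysis around a transcritical singularity,
hybrid (integrate-and-reset) models, and detectors for the burst
signature of high calcium conductance. Written for computational
neuroscientists who want the machinery of the revised FitzHugh-style
phase portrait — hourglass nullcline, latency funnel,
afterdepolarization — as tested, scriptable R.

## The model

The package starts from the Hodgkin–Huxley equations (original squid
constants, shifted convention) augmented with a non-inactivating,
slowly activating calcium current and a constant pump current:

    C dV/dt = −ḡ_Na m³h (V−V_Na) − ḡ_K n⁴ (V−V_K) − ḡ_L (V−V_L)
              − ḡ_Ca d (V−V_Ca) + I_pump + I_app(t)

with first-order gates and the calcium activation `d` gating on the
potassium timescale. The classical reduction (m instantaneous,
`h = 0.866 − 1.053 n`, `d = 1.5 n³`) yields a planar system whose
voltage nullcline, in the high-calcium regime, is an hourglass: a
hyperpolarized stable node on the left branch, a saddle and a repulsive
branch on the right, and — at a critical current — a transcritical
crossing with local normal form `dv/dt = v² − w²` in place of the
classical fold `dv/dt = v² + w`. The same structure is exercised in a
thalamocortical relay model (tonic vs T-current burst modes) and
distilled into hybrid models

    dv/dt = v² − k w² + I − z ,  dw/dt = ε(a v − w + w₀) ,
    dz/dt = −ε_z z ,             reset: v→c, w→w+d_w, z→z+d_z

where the sign of `w₀` alone — the image of the calcium conductance —
switches the cell between tonic spiking and a delayed plateau burst
with an afterdepolarization.

## Worked example

```r
library(hourglass)

## step response of the high-calcium fixture (g_Ca = 3, I_pump = −15.6,
## step +10 uA/cm^2 at 20 ms for 60 ms)
tr <- simulate(get_fixture("hh_ca"), t_max = 250)
signature_report(tr)
#> <signature_report> burst_with_signature
#>   4 spikes; latency 19.14; plateau TRUE (floor 1.71); ADP TRUE

## the resting phase portrait of its planar reduction
pm <- reduce_hh(build_hh_ca(3, -15.6))
phase_portrait(pm, I_app = 0, manifolds = FALSE)
#> <phase_portrait> reduced_hh_ca at I = 0
#>   2 V-nullcline branch(es), 3 equilibria:
#>    (-41.395, 0.0142)  stable node
#>    (15.634, 0.5599)  saddle
#>    (23.660, 0.6635)  unstable node

## the organizing singularity
detect_transcritical(pm, c(-30, 30))[c("location", "critical_current")]
#> $location        V 4.65 mV, n 0.396
#> $critical_current  2.96
```

Reading: under the canonical step the calcium model fires with a ~19 ms
latency (ten times the plain model's), its burst rides a plateau 43 mV
above rest, and terminates in an afterdepolarization; the reduced phase
plane explains why — the rest is a hyperpolarized node separated from
the spiking branch by a saddle, and the two nullcline lobes cross in a
transcritical point at `I* ≈ 3 µA/cm²` inside the physiological range.

The same machinery covers bifurcation diagrams
(`bifurcation_diagram`, `locate_homoclinic`, `hopf_criticality`), the
thalamocortical models (`build_tc_complete`, `reduce_tc`) and the
hybrid pair (`build_tc_hybrid`, `build_fold`, `pulse_robustness`).

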