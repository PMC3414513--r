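---
title: "Calcium currents and the shape of neuronal excitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcium currents and the shape of neuronal excitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The science

The classical two-variable picture of neuronal excitability — an N-shaped
voltage nullcline crossed by a sigmoid recovery nullcline — descends from
FitzHugh's reduction of the Hodgkin–Huxley (HH) equations, where the
recovery variable `n` aggregates potassium activation and sodium
inactivation, both *hyperpolarizing* influences. Many neurons, however,
express calcium currents that are *depolarizing* yet gate on the slow
timescale of `n`. When such a current is added to the HH model before
reduction, the recovery variable inherits two antagonistic effects, the
total ionic current is no longer monotone in `n` at fixed voltage, and the
voltage nullcline acquires a second, lower branch. At rest the nullcline
takes an hourglass shape whose left branch carries a hyperpolarized stable
node; under stimulation the branches separate, and the trajectory must
crawl through the funnel between the lower branch and the recovery
nullcline. This geometry produces a triple electrophysiological
signature: a long *spike latency*, *plateau oscillations* (spiking whose
troughs stay depolarized relative to rest), and an *afterdepolarization*
(ADP) when the burst collapses.

Organizing all of this is a **transcritical singularity**: at a critical
applied current the two nullcline branches cross in an X, and the local
normal form of the fast dynamics is the indefinite quadratic `v² − w²`
rather than the fold form `v² + w` that governs the classical reduction.
The package implements this entire program: the conductance-based models,
their planar reductions, the phase-plane and bifurcation machinery that
exposes the singularity, hybrid (integrate-and-reset) models built on
the two normal forms, and detectors for the signature. Thalamocortical
(TC) relay neurons — which switch between tonic spiking and plateau
bursting as their T-type calcium current deinactivates — serve as the
worked physiological example.

## Conductance models and the frozen constants

The HH family uses the original squid-axon constants in the shifted
voltage convention (rest near 0 mV, depolarization positive):
`g_Na, g_K, g_L = 120, 36, 0.3` mS/cm², `V_K = −12` mV, with the sodium
and leak reversals rounded to `120` and `10.6` mV. The calcium-augmented
model (`build_hh_ca`) adds a non-inactivating high-threshold current
`g_Ca · d · (V − E_Ca)` and a constant hyperpolarizing pump current.
The canonical conductance/pump pairings are `(g_Ca, I_pump) = (0, 0),
(1, −0.74), (1.5, −2.78), (3, −15.6)`; the high-calcium fixture uses
`(3, −15.6)`, the only pairing whose resting portrait carries the
node–saddle–repulsive-branch structure.

Three numerical choices deserve comment, all fixed once and recorded in
`hourglass_fixture_constants`:

* **Calcium reversal `E_Ca = 80` mV (shifted).** The reversal controls
  where the spiking limit cycle is born. With `E_Ca` near or above the
  sodium reversal the cycle survives at zero current, so a burst would
  never terminate when a stimulus is released; with `E_Ca` below ~75 mV
  the three-equilibrium resting portrait disappears. The chosen value
  leaves the saddle-homoclinic cycle birth at a small positive current
  (`I_hom ≈ 3` µA/cm²), below the fold of rest states (`I_fold ≈ 7`),
  which is exactly the ordering that makes the step response burst and
  the release relax to rest.
* **Calcium gate kinetics.** The activation steady state is tied to the
  potassium activation curve through `d_inf = clip(1.5 · n_inf³)`,
  consistent with the static burst-onset relation `d = 1.5 n³` used by
  the reduction, with time constant `1.5 τ_n`. The factor makes the
  calcium conductance outlast each spike slightly; with `τ_d = τ_n`
  the post-burst calcium tail is too short to carry the trajectory over
  the nullcline funnel and the ADP hump disappears at some step-off
  phases.
* **The linear `h(n)` relation** is a least-squares fit over a tonic
  spiking trajectory, frozen at `h = 0.866 − 1.053 n` (close to the
  classical FitzHugh-style relation).

The TC relay model (`build_tc_complete`) is a standard single
compartment with Traub-type sodium/potassium kinetics (threshold shift
−55 mV), a low-threshold T-type calcium current with fast activation and
slow window inactivation at 36 °C, and ohmic plus potassium leaks
(`g_Na, g_K, g_T, g_L, g_KL = 90, 10, 2, 0.05, 0.005` mS/cm²). Holding
currents of `+0.2` and `−0.6` µA/cm² put the cell at −63.5 mV
(T inactivated, `hT ≈ 0.01`) and −82.5 mV (`hT ≈ 0.6`); a `+0.8` µA/cm²
step then evokes a regular train or a delayed high-frequency burst with
an ADP, respectively.

The canonical HH-family protocol is a step of `+10` µA/cm² (onset 20 ms,
duration 60 ms). The amplitude sits between the fold of rest states
(≈ 7 µA/cm²) and the disappearance of the lower nullcline branch
(≈ 11 µA/cm²), so that during the step the phase plane shows the two
disjoint branches whose funnel generates the latency.

## Planar reductions

`reduce_hh` applies the classical reduction — instantaneous sodium
activation, `h` linear in `n`, and (when calcium is present) the static
power law `d = 1.5 n³`, clipped to the gate range `[0, 1]` (the raw law
exceeds 1 for `n > 0.87`; clipping only affects the far-depolarized
region). The timescale ratio `eps` multiplies the recovery flow only, so
nullclines and equilibria are `eps`-invariant and the singular limit is
available to the analysis code.

`reduce_tc` merges the slow TC gates into the potassium activation
variable: `h = 0.979 − 1.328 n` and `mT = 1.583 n^0.505`, both fitted
over the burst window of the complete model. The power law is fitted in
**log space**: a linear-space fit is dominated by the large mid-burst
values and overestimates the resting T-activation seven-fold, which
injects a spurious inward current at −82 mV and destroys the
hyperpolarized rest. T-type inactivation `hT` is far slower than every
other gate and is exposed as a frozen parameter for phase-plane work;
`simulate_planar(..., dynamic_aux = TRUE)` integrates it as a third
state for time-domain comparisons. Reduced-model holding currents are
adjusted in both modes (`holding_adjustment`) so the reduced and
complete models share the resting potential — without this the reduced
burst-mode rest sits 2 mV depolarized, deinactivates less T-current, and
loses two spikes per burst.

The analysis box of the HH-family reductions is `V ∈ [−50, 120]` mV,
`n ∈ [0, 1]`. For the TC reduction the box is restricted to the
subthreshold/plateau region `V ∈ [−100, −25]`, `n ∈ [0, 0.75]`: outside
it the clipped merged-gate relations flatten and generate nullcline
pieces with no dynamical meaning.

Known limitation: in the inactivated (tonic) mode the reduced TC
nullcline shows a compact sodium-window branch carrying the rest next to
the main branch, rather than a single branch; the deinactivation
contrast (a lower branch extending to −83 mV that carries the rest only
when `hT` is large) is the property the package asserts and tests.

## Phase-plane machinery

Nullclines are extracted by marching-squares contour tracing on a fine
grid followed by one-dimensional Newton polishing of every vertex along
the steeper coordinate (residual `< 1e−8`). Contour tracing handles the
hourglass uniformly — the curve is not a graph over either axis.
Equilibria are sign changes of the recovery flow along the polished
voltage nullcline, refined by damped two-dimensional Newton iteration
(residual `< 1e−9`, dedup radius `1e−5` box-normalized) and classified
from the finite-difference Jacobian. Saddle manifolds are integrated
from `1e−4` box-normalized eigenvector perturbations, backward for the
stable pair, with termination at the box boundary.

`detect_transcritical` solves `f = ∂f/∂V = ∂f/∂n = 0` in `(V, n, I)`
from a grid of Newton starts and keeps solutions whose Hessian is
indefinite (an X-shaped self-intersection); definite solutions are
isolated lobe births/deaths, not transcritical points. The search uses
the *smooth extension* of the static gate relations: the classical
model's singularity lies at negative `n`, where the clipped `h`
relation would flatten the field and erase the very structure being
sought. This is also why the singularity is reported together with an
`inside_box` flag: physiological for the calcium model
(≈ `(4.6 mV, 0.40)` at `I* ≈ 3`), outside the box (negative recovery)
for the classical one. `normal_form_coefficients` labels a point
`"transcritical"` (vanishing gradient, indefinite quadratic) or
`"fold"` (non-zero `∂f/∂n` with non-degenerate curvature, the `v² + w`
structure at a nullcline knee).

## Bifurcation analysis

`continue_equilibria` sweeps the current, tracking each equilibrium by
Newton prediction from the previous step with periodic full re-scans to
pick up newly born branches, then links points into branches by
proximity. For planar systems this is as reliable as pseudo-arclength
continuation — the global scan is cheap and fold passages appear as
branch merges — and it keeps the engine free of dedicated continuation
dependencies. Folds are refined by solving `f = g = det J = 0`, Hopf
points by `f = g = tr J = 0`. Hopf criticality uses the first Lyapunov
coefficient of the planar field (third-order finite differences in
eigen-coordinates); when the coefficient is below resolution a
simulation probe just past the Hopf decides by attractor amplitude.

Limit cycles are located by simulation with a Poincaré-style peak
analysis: transients of ten slow time constants are discarded and a
cycle is accepted when at least five consecutive inter-peak intervals
agree within 1%. `locate_homoclinic` bisects on cycle existence while
verifying a saddle exists throughout (it refuses otherwise — in the
classical model the cycle dies in a saddle-node of limit cycles, and
the refusal is the correct diagnosis). Near the connection the period
grows logarithmically (measured `≈ −8.7 ln δI` ms); the package asserts
this log divergence rather than any fixed period ratio, which a
homoclinic cannot honor.

## Hybrid models

The transcritical hybrid model integrates

```
dv/dt = v² − k w² + I − z
dw/dt = eps (a v − w + w0)
dz/dt = −eps_z z
```

with reset `v → c, w → w + d_w, z → z + d_z` at `v = v_threshold`,
events located by the solver's root finder. Defaults (dimensionless):
`k = 1, a = 0.25, eps = 0.05, w0 = ±0.2, eps_z = 0.002, d_z = 0.01,
c = −0.1, d_w = 0.2`, threshold 2, drive `−0.5` off / `+0.0625` on. The
off-drive puts the v-nullcline in its lateral-branch configuration; the
on-drive opens a corridor of width `√I_on − |w0| = 0.05`, which is what
makes the high-calcium latency long. The sign of `w0` alone selects the
mode: positive places the rest above the X (tonic), negative below it
(latency, plateau burst, ADP). `z` is the image of intracellular
calcium and the pump current it activates: linear decay with a
spike-triggered increment; the burst terminates when `z` accumulates
past the corridor width, i.e. through a hybrid saddle-homoclinic event,
and the post-burst trajectory rides the attracting lower branch through
the funnel — the ADP apex. Because an attractor sets that apex, reset
perturbations of ±10% move its amplitude by ≈ 1–2%.

The fold baseline replaces the fast equation by `v² − w + I − z`
(parabolic nullcline) with `eps = 0.3, w0 = −0.05, d_w = −0.3,
d_z = 0.0605, c = −0.2`. The spike-triggered recovery *decrement* plus
fast recovery reproduce the reset-driven depolarized after-potential of
quadratic integrate-and-fire models: the hump is manufactured by the
reset landing below the nullcline, not by an attractor, so its height
tracks the reset point (±10% reset perturbations move it by ~65%) and
its apex rides near the saddle's stable manifold. `d_z` is set just
above the value at which a fourth burst spike would fire, so the
nominal burst barely terminates — a small current pulse at the apex
(amplitude 0.05, found by an upward sweep) tips it into an extra spike
that the transcritical model absorbs.

## Signature detectors

`signature_report` measures, on any voltage trace: spike times (upward
threshold crossings with a 2 ms refractory period, or the recorded
reset events for hybrid traces), latency from the stimulus edge (read
from the `i_app` column), the plateau flag (inter-spike floor more than
`margin_frac` of the spike amplitude above the pre-stimulus median
rest), and the ADP flag (a post-burst local maximum, after a 2 ms blank
covering the final spike's own peak, below the spike range, away from
stimulus discontinuities, and at least 5% of the spike amplitude above
the final rest measured over a trailing settle window). The plateau
margin default is 0.18 of the spike amplitude: the canonical
conductance fixtures sit at −9% (plain model, troughs undershoot rest)
and +29% (calcium model), so the classification is unchanged when the
margin is halved or doubled. The hybrid fixtures sit closer to the
margin (reset models pin the burst floor at the reset voltage), which
is why the margin-invariance property is asserted on the conductance
fixtures.

## What the study conditions do and do not show

All inputs are generated by the package itself under fixed, documented
protocols; there is no external data. Passing tests therefore
demonstrate internal consistency of the models, reductions and
detectors under deterministic, noise-free, single-compartment
conditions with idealized square stimuli. They do not speak to channel
noise, temperature dependence beyond the embedded rate scalings,
dendritic structure, or quantitative fits to recordings. The merged-gate
static relations are least-squares artifacts of specific trajectories:
the reduced TC model reproduces counts and timing of the complete model
to within one spike over the documented windows (a full burst; a 75 ms
tonic window — the reduced tonic rate runs ~40% slow, so longer windows
drift beyond one spike), not beyond them.

Problem sizes were chosen so the whole suite runs comfortably on one
core: nullcline grids of 400–500 points per axis (2000 for the
brute-force cross-check), continuation sweeps of ~50–60 current values,
and simulation horizons of 80–700 time units.

## Reconstruction limits

Two properties of the source system could not be reproduced by any
admissible parameter choice and are documented as such. First, the
repulsive-branch equilibrium of the calcium model's resting portrait is
an unstable *node* here (eigenvalues ≈ +20, +0.04 ms⁻¹) rather than an
unstable focus: at that location the fast eigenvalue is set by the
regenerative sodium slope and no choice of the free constants makes the
pair complex. Second, the total-ionic-current profile at fixed voltage
begins with a microscopic rise (the sodium-inactivation slope
contributes a small positive constant to `dI/dn` while the calcium term
grows only as `n²`), so the profile's honest sign-change count is two,
the first confined below `n ≈ 0.05` at 0.1% of the profile's range —
invisible at figure scale but present on any sufficiently fine grid.
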