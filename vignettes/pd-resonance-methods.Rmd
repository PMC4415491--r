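---
title: "Subthreshold resonance in a pyloric dilator neuron model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subthreshold resonance in a pyloric dilator neuron model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pdresonance models the subthreshold frequency preference of the pyloric
dilator (PD) neuron, a pacemaker cell of the crustacean stomatogastric
pyloric network.  When a small sinusoidal current of slowly increasing
frequency (a chirp, or ZAP) is injected into such a neuron, the voltage
response peaks at a nonzero frequency: the membrane behaves as a band-pass
filter.  The package provides the conductance-based model, its quasi-active
linearization into an RLC circuit, the chirp/FFT impedance pipeline, and the
experiment drivers (knockouts, holding-potential sweeps, conductance sweeps,
component tables) needed to dissect which currents create and which merely
amplify the resonance.

## The conductance-based model

The membrane equation is current conservation over a single compartment,

$$C\frac{dV}{dt} = -I_{leak} - I_h - I_{CaT} - I_{CaS} - I_{KCa} + I_{inp},$$

with each ionic current of the form $I_i = \bar g_i m_i^{r} h_i^{q}(V-E_i)$
(positive outward) and first-order gating kinetics
$\dot x = (x_\infty(V) - x)/\tau_x(V)$.  Four active currents shape the
subthreshold band:

* $I_h$, a hyperpolarization-activated inward current ($r=1$, $E_h=-20$ mV),
  slow, opposing low-frequency voltage deflections — the classic *resonator*
  current;
* $I_{CaT}$ ($m^3h$) and $I_{CaS}$ ($m^3$), transient and persistent calcium
  currents with a shared constant reversal $E_{Ca}$ — *amplifier* currents,
  since depolarization recruits more inward current (positive feedback);
* $I_{KCa}$ ($m^4$), a calcium-dependent potassium current whose activation
  is the product of a Boltzmann voltage factor and a saturating calcium
  factor $[Ca]/([Ca]+K_d)$.

Intracellular calcium follows first-order buffering driven by the calcium
currents,

$$\tau_{Ca}\frac{d[Ca]}{dt} = -F\,(I_{CaT}+I_{CaS}) - [Ca] + C_0,$$

so at a clamped potential $[Ca]^* = C_0 - F(I^*_{CaT}+I^*_{CaS}) \ge C_0$
(the calcium currents are inward).  Because $E_{Ca}$ is held constant, the
equilibrium at any holding potential is closed-form
(`find_equilibrium()`), and holding potentials are set the way an
experimenter sets them: by a computed DC holding current, not by moving the
leak reversal.

### Units and parameter provenance

All computation uses absolute per-cell units — mV, ms, nA, µS, nF, µM — in
which MΩ·nF = ms.  The published parameter table for this model mixes unit
conventions (conductances labelled per-area, capacitance absolute, and a
component table consistent with conductances read as mS), so three
constants cannot be taken at face value and were fixed by cross-checks
against the published circuit-component table, the only quantitative anchor
that couples them:

* **$E_{Ca}$** (no published value).  The linearized CaT/CaS activation
  branches scale as $1/(V^*-E_{Ca})$; matching their published resistances
  at $V^*=-55$ mV gives $V^*-E_{Ca} \approx -109$ mV, i.e. $E_{Ca} = 54$ mV
  (default, config-exposed).  This keeps $V-E_{Ca}$ large and negative
  throughout the subthreshold range, which is what makes the calcium
  branches negative (amplifying).
* **h activation midpoint/slope.**  The printed activation curve
  (midpoint −48.5 mV, slope 4.8) saturates by −65 mV, which would make the
  well-documented h-dependent resonance at −80 mV impossible and disagrees
  with the published $R_{h0}$ and $R_{hm}$ by an order of magnitude.  The
  ancestral PD-soma model's values (midpoint −70 mV, slope 6 mV) reproduce
  both, and are the default (`h_half`, `h_slope` in the config).
* **$K_d$ of the KCa calcium factor** = 30 µM: the value consistent with
  the published $R_{KCa0}$ (half-saturation at 3 µM would make it 6× too
  small).

The leak reversal is not free: it is computed at construction so that the
control resting potential (−55 mV) is an equilibrium under zero input
current, per the published footnote.  With the defaults this gives
$E_{leak} \approx -60.6$ mV.

## Quasi-active linearization

Perturbing every state about an equilibrium and dropping terms beyond first
order turns each gating variable into one admittance term $a/(p + 1/\tau^*)$
($p$ the rate variable, 1/ms), which is electrically a series
resistor–inductor branch with $L = 1/a$, $R = (1/\tau^*)/a$; the gating
steady state itself contributes an instantaneous conductance
$\bar g\,m^{*r}h^{*q}$.  The membrane capacitance and the leak close the
circuit: the full model linearizes to a capacitor, five parallel
conductances, and nine RL branches (`assemble_linear_circuit()`), four from
the voltage-gated gates (m\_CaT, h\_CaT, m\_CaS, m\_h) and five from KCa.

The KCa channel needs the extra step that distinguishes this model.  Its
activation perturbation has two inputs: voltage directly, and calcium, which
is itself driven by the *linearized CaT and CaS currents* through the
buffering equation,

$$\delta[Ca] = -\frac{F/\tau_{Ca}}{p + 1/\tau_{Ca}}\,
  \big(\delta I_{CaT} + \delta I_{CaS}\big).$$

The resulting KCa admittance is a rational function with five simple poles:
$1/\tau_{mKCa}$, $1/\tau_{Ca}$, $1/\tau_{mCaS}$, $1/\tau_{hCaT}$,
$1/\tau_{mCaT}$.  Partial-fraction expansion over those poles reduces it to
exactly five series RL branches (KCa1–KCa5), one per pole — which is why the
published branch time constants $L/R$ equal exactly those five time
constants, and why the sign of KCa1 (the branch at the KCa-activation pole)
depends on rate differences such as $1/\tau_{Ca} - 1/\tau_{mKCa}$: they are
the residue denominators.  At the control rest, KCa1 is negative
(amplifier-like) while KCa2–KCa5 are positive and dominate, so KCa as a
whole acts as a resonator — negative feedback between its conductance and
depolarization.

`classify_branch()` encodes the electrical reading: positive $R, L$ means an
inductive, negative-feedback, high-pass branch (resonator); negative $R, L$
means a capacitor-like, positive-feedback branch (amplifier).  For the
calcium activation branches the negativity traces entirely to
$V^*-E_{Ca}<0$.

### The calcium-perturbation convention (`dca_scale`)

One further unit inconsistency in the source had to be resolved: the
published KCa branch values are reproducible (to within a few percent, all
five branches and both signs) only when the calcium perturbation is driven
by currents in the same mS-based convention as the published resistance
columns — numerically 1000× the nA-based currents that set the published
steady state.  No single self-consistent gain reproduces them.  The
linearization therefore exposes `dca_scale`:

* `dca_scale = 1000` (default) — reproduces the published component table;
* `dca_scale = 1` — the strict small-signal derivative of the simulated
  model (used by the DC-conductance identity test).

The two differ only in the KCa feedback branches, which at the control rest
carry ~10⁻⁵ µS against a total of ~0.5 µS, so impedance-level comparisons
between the circuit and the nonlinear model are insensitive to the choice.
For the reader, that smallness is itself the main caveat below.

## Stimulus, impedance estimation, resonance metrics

The chirp is $I(t) = I_{amp}\sin(2\pi f(t)t)$ with
$f(t) = f_0 + (f_{max}-f_0)\,t/2T$, so the *instantaneous* frequency
$d[f(t)t]/dt$ sweeps linearly $f_0 \to f_{max}$ over $[0,T]$ (the /2T is
deliberate; without it the sweep would end at twice the nominal band).
Defaults: 0→5 Hz over 10 s, $I_{amp}=0.5$ nA — chosen to keep the voltage
deflection under ~3 mV at rest, inside the regime where the quasi-active
approximation holds; the amplitude is config-exposed and results are stable
between 0.1 and 1 nA.

Impedance is the spectral ratio $Z(f) = \mathrm{FFT}(V)/\mathrm{FFT}(I)$
after mean removal, evaluated at bins up to 5 Hz with a relative floor on
the current spectrum.  Numerical choices, each declared rather than
inherited:

* **No taper.**  The chirp occupies the full record and starts/ends near
  zero; a window would distort exactly the low-frequency bins where the
  resonance lives.
* **Ring-down padding.**  2 s of zero input are appended to the sweep
  (`pad` argument).  Without it, the response still owed to the final sweep
  cycles is truncated and every bin is biased by several percent; with it
  the pipeline matches closed-form impedances to better than 0.1% (the
  fixture tests assert 1%).
* **Smoothing.**  The nonlinear model's magnitude profile carries harmonic
  ripple; it is smoothed by locally weighted linear regression (lowess,
  zero robustness iterations) with span 0.1 of the bins.  Circuit and
  closed-form profiles are analysed unsmoothed.  Local *linear* regression
  passes constants and straight lines through unchanged, so it cannot
  manufacture a peak.
* **Peak refinement.**  A 10 s record gives ~0.08 Hz bins; the resonance
  frequency is refined by parabolic interpolation through the peak bin and
  its neighbours.
* **Q-factor.**  $Q = |Z(f_{res})|/|Z(0.5\,\mathrm{Hz})|$ with the 0.5 Hz
  magnitude linearly interpolated; $Q \ge 1.01$ counts as resonant.
  Frequencies below 0.1 Hz are excluded from the peak search; a profile
  whose maximum sits on that boundary has no interior peak and reports
  $f_{res}$ absent with $Q = 1$.

## Integration

Both the nonlinear model and the circuit are integrated by fixed-step
classical RK4 on the stimulus grid (default dt = 0.05 ms, ≥ 20 samples per
cycle at 5 Hz and ~100× below the fastest gating time constant), with the
stimulus linearly interpolated at half-steps.  A fixed step — rather than an
adaptive solver — keeps the output on the uniform grid the FFT needs and
makes runs bit-reproducible.  The cores are compiled (Rcpp); a plain-R
right-hand side and RK4 step are exported/kept in the tests as the oracle
the compiled path must match step-for-step.  Step-halving changes a 2 s
chirp response by ~10⁻⁹ relative.

Negative-element branches make the linear circuit potentially stiff in the
wrong direction: before integrating, the eigenvalues of the state matrix
scaled by dt are checked against the RK4 stability polynomial and the run
refuses a step outside the region.  Simulations start exactly at the
equilibrium (nonlinear) or at zero (circuit), so no transient needs
discarding.

## Synthetic fixtures: what they do and do not show

`make_reference_rlc()` builds a single-branch parallel RLC-with-leak
circuit whose impedance is evaluated in closed form by an independent code
path (`reference_impedance()`), and whose resonance is located from that
closed form by direct maximization — never by the FFT pipeline under test.
The defaults (C = 1 nF, g\_L = 0.05 µS, R = 10 MΩ, L = 10⁴ MΩ·ms) put the
peak near 1.9 Hz with Q ≈ 1.27, inside the chirp band.
`generate_noisy_profile()` adds seeded Gaussian noise to a known magnitude
curve to exercise the smoother's argmax recovery.

These fixtures validate the *pipeline* — transfer estimation, smoothing,
peak metrics — against analytic truth.  They do not emulate experimental
recordings: no electrode or synaptic noise, no drift, no spike
contamination.  Passing them says the numerics are right, not that the
biological model is.

## Scope, known limitations, irreproducible values

* The model is a single compartment and strictly subthreshold: no spiking
  or bursting, no AB neuron, no stochastic channel gating.  The quasi-active
  circuit is meaningful only for small perturbations.
* With the physically consistent calcium gain ($F$ = 0.515 µM/nA as
  printed), the steady-state KCa conductance at subthreshold potentials is
  tiny ($m^{*4}\sim10^{-9}$), so the *simulated nonlinear* model's
  resonance is h-driven everywhere.  Its hyperpolarized behaviour matches
  the published account well (Q ≈ 1.35 at −80 mV vs 1.28; Q rising to
  ≈ 1.58 at −64 mV vs 1.67; h-knockout abolishes resonance; calcium
  knockout has no effect there).  The published *depolarized* behaviour
  (Q ≈ 2.35 near −50 mV, Q = 1.24 at −53 mV, resonance at 1.3 Hz at
  −55 mV vs 1.63 here) is **not** reproduced: it would require a calcium
  feedback two to three orders stronger than the printed constants provide,
  and no documented reading of the source's units yields it consistently.
  The acceptance checks assert the published values at face value and are
  expected to fail there; the component-table and property-based checks
  pass.
* The re-expression of negative R–L branches as positive-element RC
  networks is out of scope; branches are classified by sign only.

## Problem sizes

Default analyses integrate 240 001 samples per condition (10 s sweep + 2 s
pad at 0.05 ms) in well under a second each (compiled core); the 16-point
holding-potential sweep completes in a few seconds.  The test-suite
equilibrium, convergence and fidelity checks use 1–10 s records at the same
step.
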