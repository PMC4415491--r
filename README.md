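# pdresonance

Subthreshold membrane resonance analysis for the pyloric dilator (PD)
neuron of the crustacean stomatogastric ganglion.

Pacemaker neurons like PD prefer inputs at particular frequencies: injected
with a small chirp (ZAP) current whose frequency sweeps slowly upward, their
membrane impedance $|Z(f)|$ peaks at a nonzero resonance frequency
$f_{res}$.  This band-pass behaviour arises from the interplay of the
passive membrane (a low-pass RC element) with slow voltage-gated currents
that oppose low-frequency deflections (a high-pass RL arm).  Which currents
*create* the resonance and which merely *amplify* it is hard to separate
pharmacologically — blocking calcium currents unavoidably silences the
calcium-dependent potassium current too — so this package takes the
modelling route:

* a Hodgkin–Huxley-type PD model with $I_h$, $I_{CaT}$, $I_{CaS}$,
  $I_{KCa}$, leak, and first-order intracellular calcium buffering,
  integrated by a compiled fixed-step RK4 core;
* its **quasi-active linearization** about any holding equilibrium into an
  equivalent electrical RLC circuit: membrane capacitance, per-channel
  instantaneous conductances, and nine series RL branches — one per
  voltage-gated gating variable plus five KCa branches obtained by
  partial-fraction expansion of the calcium-feedback admittance over its
  five poles;
* a chirp → FFT impedance pipeline with local-regression smoothing and
  resonance metrics ($f_{res}$, $|Z|_{max}$, and the Q-factor
  $Q = |Z(f_{res})|/|Z(0.5\,\mathrm{Hz})|$, with $Q \ge 1.01$ counting as
  resonant);
* experiment drivers for channel knockouts, holding-potential sweeps,
  conductance sweeps, the amplified-KCa demonstration, and the circuit
  component table.

Branches with positive R and L are **resonators** (negative feedback,
high-pass; $I_h$ and the dominant KCa branches); branches with negative R
and L are **amplifiers** (positive feedback, capacitor-like; the calcium
activation branches, negative because $V - E_{Ca} < 0$ below threshold).

## Worked example

```r
library(pdresonance)

params <- pd_control_params()          # control condition, -55 mV rest
res <- run_condition(params, V_hold = c(-80, -55))
print(res[, 1:5], digits = 3)
#>   V_star f_res Z_max    Q is_resonant
#> 1    -80  3.91  2.34 1.35        TRUE
#> 2    -55  1.63  5.46 1.08        TRUE
```

Each row equilibrates the model at the holding potential (computed holding
current), superimposes a 0→5 Hz, 10 s, 0.5 nA chirp, and reads the
resonance off the smoothed FFT impedance profile: at the control rest the
model resonates at ~1.6 Hz with a modest Q; hyperpolarized to −80 mV the
h-current makes the resonance sharper (Q ≈ 1.35).  Setting `overrides =
c(h = 0)` abolishes the −80 mV resonance entirely, while `c(Ca = 0)` leaves
it untouched — the h-current is the hyperpolarized resonator.

The equivalent-circuit view of the same equilibrium:

```r
tab <- reproduce_table3(params)        # publication-convention units
print(head(subset(tab, !is.na(class)), 5), digits = 3)
#>   channel component        R         L     class
#> 5     CaT     m_CaT  -2.9776 -0.015198 amplifier
#> 6     CaT     h_CaT 137.6366 11.799593 resonator
#> 7     CaS     m_CaS  -0.5973 -0.008468 amplifier
#> 8       h       m_h   0.0112  0.000977 resonator
#> 9     KCa      KCa1 -79.4588 -4.775304 amplifier
```

The calcium activation branches and the first KCa branch carry negative
elements (amplifiers); everything else is a resonator.  See the methods
vignette (`vignettes/pd-resonance-methods.Rmd`) for the model equations,
the unit system, the documented calibrations ($E_{Ca}$, the h-activation
midpoint, the KCa calcium-factor $K_d$, the calcium-perturbation
convention), and the numerical choices behind the pipeline.

A thin command-line driver wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pdresonance.R",package="pdresonance"))')" \
    sweep-v --potentials=-64:-49 --out results/
```

with subcommands `simulate`, `linearize`, `impedance`, `knockout`,
`sweep-v`, `sweep-g`, `table3`, `amplified-kca`; model parameters come from
a flat YAML config (see `inst/extdata/control.yaml`).

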