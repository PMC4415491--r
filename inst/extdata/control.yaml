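# Control condition of the PD neuron model.
# Flat key-value config; keys mirror the arguments of pd_control_params().
# Units: conductances uS, potentials mV, capacitance nF, times ms,
# concentrations uM, F_Ca uM/nA.
g_h: 0.219
g_CaT: 2.25
g_CaS: 5.4
g_KCa: 150
g_leak: 0.105
E_h: -20
E_K: -80
E_Ca: 54          # constant calcium reversal (calibrated; see vignette)
C: 12
tau_Ca: 300
C0: 0.5
F_Ca: 0.515
Kd: 30
V_rest: -55       # E_leak is computed so this is the zero-input rest
h_half: -70
h_slope: 6
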