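# Machine-readable connection-parameter tables.
# static: within-space excitatory/inhibitory wiring (weights fixed).
# plastic: excitatory-to-excitatory connection types with STDP parameters.
# Weights are in tabulated weight units; the membrane-potential jump per
# unit is set by the w_unit_* scales of the model parameters.
static:
  EI: {p: 0.575, w: 17.39, delay: 0.5}
  IE: {p: 0.600, w: -4.76, delay: 0.5}
  II: {p: 0.550, w: -16.67, delay: 0.5}
plastic:
  X_C:  {p: 1.0, delay: [1, 10], init: [0.0, 0.8], bounds: [0, 0.8],
         alpha: 0, tau_plus: 25, tau_minus: null, A_minus: 0.4, eta: 0.01}
  S_C:  {p: 0.1, delay: [1, 10], init: [0.19, 0.39], bounds: [0, 0.87],
         alpha: 0, tau_plus: 20, tau_minus: null, A_minus: 0.47, eta: 0.008}
  EE_C: {p: 0.1, delay: [1, 1], init: [0.0, 0.0], bounds: [0, 0.6],
         alpha: -1, tau_plus: 25, tau_minus: 40, A_minus: 0.5, eta: 0.0025}
  C_S:  {p: 0.1, delay: [1, 10], init: [0.48, 0.86], bounds: [0, 1.33],
         alpha: 0, tau_plus: 21, tau_minus: null, A_minus: 0.28, eta: 0.004}
  EE_S: {p: 0.1, delay: [1, 1], init: [0.44, 0.87], bounds: [0, 1.08],
         alpha: -1, tau_plus: 37, tau_minus: 49, A_minus: 0.52, eta: 0.006}
# Short-term depression of the comparison readout synapses.  The values
# are literature-derived stand-ins for a strongly depressing facilitating
# synapse type (the cited source does not print them).
readout_tm: {U: 0.25, tau_rec: 700, tau_fac: 20, w: 50, literature_derived: true}
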