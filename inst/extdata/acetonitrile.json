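{
  "name": "acetonitrile",
  "temperature": 298.15,
  "probe_radius": 2.49,
  "alpha_A": -0.00531,
  "gamma_N": 1.0,
  "W_R": -2.0,
  "eta": 1.5,
  "E_R": -12.0,
  "rt_ln_conc": 1.75,
  "dG_solv_solvent": -4.19,
  "proton_solvation_anchor": -253.2
}
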