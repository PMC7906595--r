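{
  "params": {
    "mu_max0": 0.244,
    "K_s": 11.5,
    "Z_m": 60,
    "K_z": 0.83,
    "family": "exponential"
  },
  "yields": {
    "Y_xs": 0.28,
    "Y_ps": 0.42,
    "Y_zs": 0.0442
  },
  "mixture": {
    "frac_glycerol": 0.56,
    "frac_acetic": 0.36,
    "frac_succinic": 0.08
  },
  "initial": {
    "X0": 1,
    "S0": 100,
    "P0": 0,
    "Z0": 0
  },
  "grid": {
    "t_end": 72,
    "dt": 0.01
  },
  "threshold_fraction": 0.01,
  "noise": {
    "relative_sd": 0.05,
    "floor_sd": 0
  },
  "seed": 1
}
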