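{
  "experiment": "simulate",
  "params": { "n": 10, "eps1": 0.01, "eps2": 1e-4, "sigma": 0 },
  "config": { "n_steps": 20000, "seed": 1 },
  "scale": 1.0
}
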