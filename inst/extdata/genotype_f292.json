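{
  "genotype": "F292",
  "k1max": 0.1,
  "k2max": 0.047,
  "k3max": 0.001,
  "e1": 0.4,
  "e2": 0.3,
  "e3": 0,
  "g": 0.001,
  "bc_max": 0.05,
  "lci_t": 0.46,
  "lci_max": 0.7,
  "k_b11": 10,
  "k_b22": 23,
  "k_b32": 300,
  "k_b33": 500,
  "c1": 361,
  "c1t_fraction": 0.71,
  "c2": 1295,
  "c3": 344,
  "b1": 10,
  "b2": 10,
  "b3": 5
}
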