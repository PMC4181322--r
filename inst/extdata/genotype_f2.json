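{
  "genotype": "F2",
  "k1max": 0.1,
  "k2max": 0.047,
  "k3max": 0.001,
  "e1": 0.4,
  "e2": 0.3,
  "e3": 0,
  "g": 0.001,
  "bc_max": 0.05,
  "lci_t": 0.42,
  "lci_max": 0.7,
  "k_b11": 10,
  "k_b22": 29,
  "k_b32": 300,
  "k_b33": 500,
  "c1": 364,
  "c1t_fraction": 0.61,
  "c2": 1238,
  "c3": 397,
  "b1": 10,
  "b2": 10,
  "b3": 5
}
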