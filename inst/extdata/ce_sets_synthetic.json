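[
  {
    "expert": "expert_A_style",
    "comment": "synthetic: averse at poor (0.25) and good (0.75) state, slightly prone at the moderate state (CE 0.6 > 0.5)",
    "x25": 0.2,
    "x50": 0.6,
    "x75": 0.7
  },
  {
    "expert": "expert_B_style",
    "comment": "synthetic: slightly averse at all three probed states",
    "x25": 0.2,
    "x50": 0.45,
    "x75": 0.7
  },
  {
    "expert": "expert_C_style",
    "comment": "synthetic: slightly averse at all three probed states",
    "x25": 0.18,
    "x50": 0.44,
    "x75": 0.68
  }
]
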