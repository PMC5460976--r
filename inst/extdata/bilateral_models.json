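[
  ["S1"],
  ["S2"],
  ["IFG"],
  ["IPC"],
  ["S1", "S2"],
  ["S1", "IFG"],
  ["S1", "IPC"],
  ["S2", "IFG"],
  ["S2", "IPC"],
  ["S1", "S2", "IFG"],
  ["S1", "S2", "IPC"],
  ["S1", "S2", "IFG", "IPC"]
]
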