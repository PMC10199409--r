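{
  "internalised": ["Precuneus", "vmPFC", "dmPFC", "ATL", "AG"],
  "control": ["IFG", "OFC"],
  "ventromedial": ["ATFP", "Amygdala"]
}
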