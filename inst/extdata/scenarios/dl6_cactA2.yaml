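# dl6/cactA2 double mutant: both total Dorsal and Cactus synthesis
# reduced; total Cactus is an output, not an input.
name: dl6_cactA2
overrides:
  Dl_tot: 0.375
  k1: 0.500
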