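# cactA2/cact011 hypomorph: reduced Cactus synthesis constant k1.
name: cactA2_cact011
overrides:
  k1: 0.1825
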