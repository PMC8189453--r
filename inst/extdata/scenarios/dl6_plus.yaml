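# Embryos from dl6/+ mothers: reduced maternal Dorsal, Cactus synthesis
# unchanged.
name: dl6_plus
overrides:
  Dl_tot: 0.4605
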