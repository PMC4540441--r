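name: management
temp_delta: 0.0
cyclone_multiplier: 1.0
shifts:
  nutrients: -1.0
  sediment: -1.0
  pollution: -1.0
  fishing: -1.0
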