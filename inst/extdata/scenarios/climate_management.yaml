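name: climate_management
temp_delta: 0.2
cyclone_multiplier: 1.3
shifts:
  disease: 1.0
  bleaching: 1.0
  nutrients: -1.0
  sediment: -1.0
  pollution: -1.0
  fishing: -1.0
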