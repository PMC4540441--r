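name: baseline
temp_delta: 0.0
cyclone_multiplier: 1.0
shifts: []
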