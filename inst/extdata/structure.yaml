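nodes:
  temperature:
    kind: input
    states:
    - below
    - average
    - above
  cyclones:
    kind: input
    states:
    - below
    - average
    - above
  irradiance:
    kind: input
    states:
    - below
    - average
    - above
  nutrients:
    kind: input
    states:
    - below
    - average
    - above
  sediment:
    kind: input
    states:
    - below
    - average
    - above
  pollution:
    kind: input
    states:
    - below
    - average
    - above
  fishing:
    kind: input
    states:
    - below
    - average
    - above
  water_quality:
    kind: composite
    states:
    - low
    - medium
    - high
    parents:
    - nutrients
    - sediment
    - pollution
  anthropogenic_stress:
    kind: composite
    states:
    - low
    - medium
    - high
    parents:
    - fishing
    - water_quality
  bleaching:
    kind: event
    states:
    - decreased
    - unchanged
    - increased
    parents:
    - temperature
    - irradiance
    - water_quality
  disease:
    kind: event
    states:
    - decreased
    - unchanged
    - increased
    parents:
    - temperature
    - water_quality
  cots:
    kind: event
    states:
    - decreased
    - unchanged
    - increased
    parents:
    - water_quality
  decline:
    kind: outcome
    states:
    - no_decline
    - decline
    parents:
    - bleaching
    - disease
    - cots
    - cyclones
    - anthropogenic_stress
composite_weights:
  water_quality:
    nutrients: 1.0
    sediment: 1.0
    pollution: 1.0
  anthropogenic_stress:
    fishing: 1.0
    water_quality: 1.0
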