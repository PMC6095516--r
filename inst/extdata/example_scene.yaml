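# Example scene specification for `dtrack simulate`: two circuits of the
# deep area, a spell of diving, and a dwell near the gate.
pixel_noise_sigma: 0.5
segments:
  - type: circle
    centre: [0.0, 0.0]
    radius: 5.5
    turns: 2
    duration_s: 30
    depth: 1.2
  - type: dive
    position: [2.0, 1.0]
    depth_range: [0.5, 4.0]
    period_s: 8
    duration_s: 16
  - type: dwell
    position: [8.0, 0.0, 0.8]
    duration_s: 5
    jitter_m: 0.05
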