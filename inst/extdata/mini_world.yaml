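arena: 3.0
visual_seed: 21
frame_every_rows: 25
lap_rows: 600
'N': 40
'n':
- 2
- 3
- 4
- 5
depth_max: 4.5
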