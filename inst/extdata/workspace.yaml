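bounds:
- 0.0
- 20.0
- 0.0
- 20.0
obstacles:
- - 4.7708881
  - 9.5117625
  - 2.2905974
  - 7.9581005
- - 11.6613272
  - 16.4655571
  - 14.2840268
  - 18.3958668
- - 8.6314966
  - 11.0733086
  - 5.7464042
  - 8.839544
- - 3.7784708
  - 8.0151622
  - 6.7933655
  - 9.8437381
resolution: 0.1
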