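isotope: I-125
activity_per_seed: 0.36
dose_levels:
- 110.0
- 145.0
rows:
- volume: 10.0
  '110': 31.0
  '145': 43.0
- volume: 15.0
  '110': 38.0
  '145': 50.0
- volume: 20.0
  '110': 45.0
  '145': 57.0
- volume: 25.0
  '110': 52.0
  '145': 64.0
- volume: 30.0
  '110': 59.0
  '145': 71.0
- volume: 35.0
  '110': 66.0
  '145': 78.0
- volume: 40.0
  '110': 73.0
  '145': 85.0
- volume: 45.0
  '110': 80.0
  '145': 92.0
- volume: 50.0
  '110': 87.0
  '145': 99.0
- volume: 55.0
  '110': 93.0
  '145': 106.0
- volume: 60.0
  '110': 100.0
  '145': 113.0
- volume: 65.0
  '110': 107.0
  '145': 120.0
- volume: 70.0
  '110': 114.0
  '145': 127.0
- volume: 75.0
  '110': 121.0
  '145': 134.0
- volume: 80.0
  '110': 128.0
  '145': 141.0
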