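{
  "days_10": {
    "threshold": 0.10,
    "events": [[21, 7], [4, 27]],
    "nonevents": [[318, 49], [24, 129]]
  },
  "days_20": {
    "threshold": 0.20,
    "events": [[57, 0], [1, 1]],
    "nonevents": [[501, 7], [1, 11]]
  },
  "episodes_10": {
    "threshold": 0.10,
    "events": [[16, 0], [0, 49]],
    "nonevents": [[355, 2], [5, 152]]
  },
  "episodes_20": {
    "threshold": 0.20,
    "events": [[33, 0], [0, 32]],
    "nonevents": [[462, 4], [0, 48]]
  }
}
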