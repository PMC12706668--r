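{
  "goal": "Older-adult mobility scooter requirements",
  "reciprocity_tol": 0.005,
  "criteria": {
    "labels": ["O", "A", "M"],
    "matrix": [
      [1, 4, 2],
      [0.25, 1, 0.5],
      [0.5, 2, 1]
    ]
  },
  "indicators": {
    "O": {
      "labels": ["O1", "O2", "O3", "O4", "O5", "O6"],
      "matrix": [
        [1, 0.2, 0.5, 0.111, 0.125, 2],
        [5, 1, 3, 0.5, 0.5, 8],
        [2, 0.333, 1, 0.25, 0.25, 3],
        [9, 2, 4, 1, 2, 9],
        [8, 2, 4, 0.5, 1, 9],
        [0.5, 0.125, 0.333, 0.111, 0.111, 1]
      ]
    },
    "A": {
      "labels": ["A1", "A2", "A3"],
      "matrix": [
        [1, 3, 1],
        [0.333333333333333, 1, 0.333333333333333],
        [1, 3, 1]
      ]
    },
    "M": {
      "labels": ["M1", "M2", "M3", "M4"],
      "matrix": [
        [1, 2, 4, 4],
        [0.5, 1, 2, 2],
        [0.25, 0.5, 1, 1],
        [0.25, 0.5, 1, 1]
      ]
    }
  }
}
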