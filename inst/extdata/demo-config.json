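{
  "out_dir": "chemotaxkit-demo",
  "axis": [1, 0],
  "simulate": {
    "dt": 0.75,
    "duration": 120,
    "speed_mean": 6.9,
    "speed_sd": 1.5,
    "groups": [
      { "name": "WT",  "n_cells": 30, "bias": 0.6, "persistence": 0.3, "seed": 101 },
      { "name": "DKO", "n_cells": 30, "bias": 0.0, "persistence": 0.3, "seed": 102 }
    ]
  },
  "filter": {
    "min_volume": 16,
    "min_path_length": 50,
    "static_displacement_threshold": 2
  },
  "compare": { "metric": "dmi", "method": "rank_sum" }
}
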