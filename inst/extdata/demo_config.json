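{
  "format": "mobflim-config/1",
  "acquisition": {
    "laser_period_ns": 12.5,
    "n_time_bins": 256,
    "harmonic": 1,
    "irf_sigma_ns": 0,
    "background_rate": 0,
    "frame_shape": [192, 192]
  },
  "populations": [
    {"preset": "HSC", "n_cells": 30},
    {"preset": "MPP", "n_cells": 30},
    {"preset": "OPP", "n_cells": 30}
  ],
  "features": {
    "tau_free_ns": 0.45,
    "band_fraction": 0.3,
    "count_threshold": 30
  },
  "gate": {
    "target": "HSC",
    "features": "all",
    "k": 3
  },
  "classifier": {
    "positive": "HSC",
    "train_populations": ["HSC", "MPP"],
    "threshold": 0.5
  },
  "seed": 20200110
}
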