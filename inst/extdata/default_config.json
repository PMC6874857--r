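{
  "grid": {
    "origin_x": 0,
    "origin_y": 0,
    "pixel_size": 500,
    "ncol": 80,
    "nrow": 80,
    "crs_note": "local planar (m)"
  },
  "n_sites": 140,
  "feature_counts": {
    "human_settlements/urban_area": 1,
    "human_settlements/village": 10,
    "mining": 4,
    "agriculture": 12,
    "hydroelectric/operating_small": 1,
    "hydroelectric/construction_medium": 1,
    "thermoelectric": 2,
    "oil/well_operating": 4,
    "oil/well_not_operating": 3,
    "oil/spill_recent_high": 1,
    "oil/pool_no_treatment": 1,
    "oil/pipeline_risky": 1,
    "oil/pipeline_out_of_risk": 1,
    "water_withdrawals": 5,
    "aquaculture": 5,
    "roads": 10
  },
  "beta0": 0.762,
  "beta": {
    "human_settlements": -0.165,
    "roads": -0.121,
    "oil": -0.136,
    "elevation": -0.176,
    "slope": 0.199
  },
  "sigma": null,
  "target_r2": 0.25,
  "scenario": "b",
  "microbasins": {
    "nx": 5,
    "ny": 5
  },
  "selection": {
    "collinearity_r": 0.7
  },
  "cv": {
    "k": 7,
    "repeats": 20
  },
  "seeds": {
    "simulation": 42,
    "cv": 1
  },
  "paths": []
}
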