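{
  "lambda1": -3.60738054251455,
  "lambda2": -2.24280833571401,
  "lambda3": 0.552955513518379,
  "gamma": 0.0682762401321673,
  "feature_config": {
    "flank_len": 20,
    "min_len": 5,
    "max_len": 9,
    "composition_stat": "topidp",
    "disorder_source": "builtin-fallback"
  },
  "provenance": {
    "description": "Fitted on synthetic example regions generated by simulate_training_set (n=2000, seed=20260930). Non-canonical demonstration parameters; retrain on curated regions for production use.",
    "training": "simulate_training_set(2000, lambda=c(-4,-2,0.6), gamma=0, seed=20260930)"
  },
  "se": [0.0516766750643091, 0.275902400887595, 0.191016344682075, 0.0389214040711339]
}
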