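{
  "version": "1.0",
  "comment": "Default simulation parameters for a Hylobius abietis biocontrol randomised-block trial. Outcome and stage probabilities are exact count fractions from the Scottish 2022 destructive-sampling cross-tabulation; emergence rate ratios are the fitted relative emergence ratios of that trial; depth/distance locations are the per-outcome field summaries.",
  "seed": 20220701,
  "n_blocks": 10,
  "treatments": ["control", "fungi", "halfmix", "nematodes"],
  "outcome_levels": ["alive", "nematode_killed", "fungus_killed", "indeterminate"],
  "stage_levels": ["larva", "pupa", "adult"],
  "outcome_probs": {
    "control":   [0.96581196581196582, 0.0, 0.017094017094017096, 0.017094017094017096],
    "fungi":     [0.69811320754716977, 0.0, 0.28301886792452829, 0.018867924528301886],
    "halfmix":   [0.45370370370370372, 0.47222222222222221, 0.018518518518518517, 0.055555555555555552],
    "nematodes": [0.46280991735537191, 0.51239669421487599, 0.0082644628099173556, 0.016528925619834711]
  },
  "stage_probs": [0.61152882205513781, 0.30827067669172931, 0.080200501253132828],
  "weevils_per_stump": 10,
  "emergence_intercept": 2.3025850929940459,
  "rate_ratios": {
    "control": 1.0,
    "fungi": 0.468,
    "halfmix": 0.393,
    "nematodes": 0.322
  },
  "block_sd": 0.3,
  "nb_dispersion": 2.0,
  "depth_model": {
    "alive":           {"mean": -16.359, "sd": 8.0},
    "nematode_killed": {"mean": -15.681, "sd": 8.0},
    "fungus_killed":   {"mean": -9.4,    "sd": 8.0},
    "indeterminate":   {"mean": -13.364, "sd": 8.0}
  },
  "distance_model": {
    "alive":           {"p_zero": 0.6, "mean": 5.86},
    "nematode_killed": {"p_zero": 0.6, "mean": 5.03},
    "fungus_killed":   {"p_zero": 0.6, "mean": 2.15},
    "indeterminate":   {"p_zero": 0.6, "mean": 3.0}
  },
  "community_taxon_means": {
    "Collembola": 30, "Diptera": 25, "Coleoptera": 18, "Acari": 15,
    "Hymenoptera": 12, "Araneae": 9, "Hemiptera": 7, "Annelida": 6,
    "Myriapoda": 5, "Isopoda": 4, "Lepidoptera": 3, "Gastropoda": 2
  },
  "community_effect": {
    "control": 1.0, "fungi": 1.0, "halfmix": 1.0, "nematodes": 1.0
  }
}
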