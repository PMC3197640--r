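{
  "presets": {
    "spontaneous_heht": {
      "twitch": {
        "peak_force_un": 61,
        "time_to_peak_s": 0.2,
        "relaxation_time_s": 0.3,
        "diastolic_force_un": 0
      },
      "schedule": {
        "base_frequency_hz": 0.5,
        "interval_cv": 0.05,
        "irregularity_mode": "regular"
      },
      "recording": {
        "duration_s": 60,
        "dt": 0.01,
        "noise_sd_un": 0.5
      }
    }
  },
  "geometry": {
    "elastic_modulus_pa": 1000000,
    "post_radius_mm": 0.5,
    "post_length_mm": 10,
    "tissue_diameter_mm": 0.72
  },
  "compounds": {
    "e4031_like": {
      "ic50_relax": 10,
      "hill_relax": 1,
      "ic50_force": 100,
      "scatter_onset": 10,
      "max_reduction": 0.4,
      "conc_unit": "nM",
      "ladder": [1, 3, 10, 30, 100]
    },
    "negative_control": {
      "ic50_relax": 1000,
      "hill_relax": 1,
      "ic50_force": 10000,
      "scatter_onset": 1000,
      "max_reduction": 0,
      "conc_unit": "uM",
      "ladder": [1, 10, 100, 300, 1000]
    }
  }
}
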