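{
  "description": "Five cognitive networks as bilateral region sets, with an editable region-name to parcellation-label dictionary. Each region expands to a left (_L) and right (_R) node. The attention network is kept as its full six-region listing; note that published link tallies for it assume fewer regions.",
  "parcellation": {
    "medial_prefrontal_cortex_L": 1, "medial_prefrontal_cortex_R": 2,
    "cingulate_cortex_L": 3, "cingulate_cortex_R": 4,
    "precuneus_L": 5, "precuneus_R": 6,
    "lateral_parietal_cortex_L": 7, "lateral_parietal_cortex_R": 8,
    "thalamus_L": 9, "thalamus_R": 10,
    "superior_parietal_lobule_L": 11, "superior_parietal_lobule_R": 12,
    "middle_frontal_gyrus_L": 13, "middle_frontal_gyrus_R": 14,
    "superior_frontal_gyrus_L": 15, "superior_frontal_gyrus_R": 16,
    "angular_gyrus_L": 17, "angular_gyrus_R": 18,
    "supramarginal_gyrus_L": 19, "supramarginal_gyrus_R": 20,
    "inferior_temporal_gyrus_L": 21, "inferior_temporal_gyrus_R": 22,
    "medial_occipitotemporal_gyrus_L": 23, "medial_occipitotemporal_gyrus_R": 24,
    "middle_temporal_gyrus_L": 25, "middle_temporal_gyrus_R": 26,
    "temporal_pole_L": 27, "temporal_pole_R": 28,
    "inferior_frontal_gyrus_L": 29, "inferior_frontal_gyrus_R": 30,
    "fusiform_gyrus_L": 31, "fusiform_gyrus_R": 32,
    "hippocampal_formation_L": 33, "hippocampal_formation_R": 34,
    "fornix_L": 35, "fornix_R": 36,
    "deep_white_matter_L": 37, "deep_white_matter_R": 38,
    "lateral_ventricles_L": 39, "lateral_ventricles_R": 40,
    "subarachnoid_csf_L": 41, "subarachnoid_csf_R": 42
  },
  "networks": [
    {
      "name": "dmn",
      "regions": ["medial_prefrontal_cortex", "cingulate_cortex",
                  "precuneus", "lateral_parietal_cortex"],
      "note": "The published five-region listing (medial prefrontal, rostral anterior cingulate, posterior cingulate, precuneus, lateral parietal) collapses to four bilateral regions because the entire cingulate cortex is treated as one region."
    },
    {
      "name": "attention",
      "regions": ["thalamus", "superior_parietal_lobule",
                  "middle_frontal_gyrus", "superior_frontal_gyrus",
                  "angular_gyrus", "supramarginal_gyrus"]
    },
    {
      "name": "verbal_memory",
      "regions": ["inferior_temporal_gyrus", "medial_occipitotemporal_gyrus",
                  "middle_temporal_gyrus", "temporal_pole", "angular_gyrus",
                  "inferior_frontal_gyrus"]
    },
    {
      "name": "memory",
      "regions": ["angular_gyrus", "fusiform_gyrus",
                  "superior_parietal_lobule", "supramarginal_gyrus",
                  "hippocampal_formation", "superior_frontal_gyrus"]
    },
    {
      "name": "visuospatial_working_memory",
      "regions": ["cingulate_cortex", "superior_frontal_gyrus", "fornix",
                  "superior_parietal_lobule", "supramarginal_gyrus"]
    }
  ]
}
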