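{
  "version": 1,
  "comment": "Per-class phantom presets: surface complexity (SH bump amplitude as a fraction of radius, highest perturbed degree), intensity heterogeneity (HU sd, correlation length mm), and mean tumor HU at the precontrast/portal-venous/delayed phases (0/80/300 s). ccRCC: most complex surface, most heterogeneous, steepest wash-in/out; nccRCC intermediate; AML smooth, homogeneous, weakly enhancing.",
  "AML": {
    "shape_bump_amplitude": 0.02,
    "shape_bump_max_degree": 3,
    "texture_sd": 12,
    "texture_correlation_length": 2,
    "enhancement": [25, 60, 50]
  },
  "nccRCC": {
    "shape_bump_amplitude": 0.08,
    "shape_bump_max_degree": 8,
    "texture_sd": 22,
    "texture_correlation_length": 3,
    "enhancement": [32, 110, 85]
  },
  "ccRCC": {
    "shape_bump_amplitude": 0.15,
    "shape_bump_max_degree": 12,
    "texture_sd": 30,
    "texture_correlation_length": 4,
    "enhancement": [35, 145, 95]
  }
}
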