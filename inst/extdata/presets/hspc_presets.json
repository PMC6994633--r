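{
  "format": "mobflim-presets/1",
  "comment": "Population presets for the synthetic FLIM generator. tau_free_ns (0.45) and the HSC tau_bound_ns anchor (3.56) follow reported hematopoietic measurements; every other value is a non-authoritative plausible default chosen to reproduce the qualitative population orderings (HSC: low ORR, high alpha_bound / tau_bound / edge enrichment / polarity).",
  "populations": {
    "HSC": {
      "means": {"orr": 0.15, "alpha_bound": 0.78, "tau_bound_ns": 3.56, "tau_free_ns": 0.45, "edge_enrichment": 1.8, "polarity_offset": 0.35, "radius_px": 7, "total_photons": 10000},
      "sds": {"orr": 0.03, "alpha_bound": 0.03, "tau_bound_ns": 0.12, "tau_free_ns": 0, "edge_enrichment": 0.15, "polarity_offset": 0.06, "radius_px": 0.5, "total_photons": 1000}
    },
    "MPP": {
      "means": {"orr": 0.28, "alpha_bound": 0.68, "tau_bound_ns": 3.05, "tau_free_ns": 0.45, "edge_enrichment": 1.25, "polarity_offset": 0.15, "radius_px": 7, "total_photons": 10000},
      "sds": {"orr": 0.05, "alpha_bound": 0.04, "tau_bound_ns": 0.15, "tau_free_ns": 0, "edge_enrichment": 0.12, "polarity_offset": 0.05, "radius_px": 0.5, "total_photons": 1000}
    },
    "OPP": {
      "means": {"orr": 0.33, "alpha_bound": 0.64, "tau_bound_ns": 2.85, "tau_free_ns": 0.45, "edge_enrichment": 1.15, "polarity_offset": 0.12, "radius_px": 7, "total_photons": 10000},
      "sds": {"orr": 0.06, "alpha_bound": 0.04, "tau_bound_ns": 0.15, "tau_free_ns": 0, "edge_enrichment": 0.12, "polarity_offset": 0.05, "radius_px": 0.5, "total_photons": 1000}
    },
    "LinNegCD45": {
      "means": {"orr": 0.40, "alpha_bound": 0.60, "tau_bound_ns": 2.60, "tau_free_ns": 0.45, "edge_enrichment": 1.0, "polarity_offset": 0.10, "radius_px": 7, "total_photons": 10000},
      "sds": {"orr": 0.06, "alpha_bound": 0.04, "tau_bound_ns": 0.15, "tau_free_ns": 0, "edge_enrichment": 0.10, "polarity_offset": 0.04, "radius_px": 0.5, "total_photons": 1000}
    },
    "CD45": {
      "means": {"orr": 0.38, "alpha_bound": 0.62, "tau_bound_ns": 2.90, "tau_free_ns": 0.45, "edge_enrichment": 1.05, "polarity_offset": 0.12, "radius_px": 7, "total_photons": 10000},
      "sds": {"orr": 0.06, "alpha_bound": 0.05, "tau_bound_ns": 0.18, "tau_free_ns": 0, "edge_enrichment": 0.12, "polarity_offset": 0.05, "radius_px": 0.5, "total_photons": 1000}
    }
  }
}
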