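{
  "package": "epifam",
  "version": "0.1.0",
  "seed": 42,
  "inputs": {
    "vcf": "study.vcf",
    "ped": "study.ped",
    "gmt": "study.gmt"
  },
  "thresholds": {
    "min_dp": 12,
    "min_mq": 30,
    "min_qd": 2,
    "max_fs": 25,
    "min_call_rate": 0.95,
    "rare_maf_ceiling": 0.01,
    "cadd_floor": 15,
    "qualifying_impacts": ["HIGH", "MODERATE", "MODIFIER"]
  },
  "pair_qc": {
    "max_missing": 0.05,
    "hwe_alpha": 0.01,
    "max_r2": 0.2
  },
  "mbmdr": {
    "alpha_cell": 0.1,
    "min_cell": 10,
    "fdr_level": 0.05,
    "perm_B": 199,
    "top_k": 1000
  },
  "delta_threshold": 10,
  "pathway": "FOCAL_ADHESION_SYN",
  "note": "Family members are treated as independent in the epistasis scan; relatedness is not modelled."
}
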