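[
  {"name": "RUE", "family": "normal", "mean": 2.72, "sd": 0.23, "units": "g MJ-1"},
  {"name": "k", "family": "normal", "mean": 0.58, "sd": 0.10, "units": "-"},
  {"name": "SLAini", "family": "normal", "mean": 35.00, "sd": 4.36, "units": "m2 kg-1"},
  {"name": "SLAtill", "family": "normal", "mean": 28.70, "sd": 3.18, "units": "m2 kg-1"},
  {"name": "BlastRes", "family": "discrete", "levels": [1, 2, 3], "units": "-"},
  {"name": "T-Chalkiness", "family": "normal", "mean": 26.4, "sd": 0.9, "units": "degC"},
  {"name": "T-HeadRice", "family": "normal", "mean": 23.9, "sd": 2.1, "units": "degC"},
  {"name": "T-ColdSter", "family": "normal", "mean": 13.5, "sd": 1.4, "units": "degC"},
  {"name": "T-HeatSter", "family": "normal", "mean": 34.4, "sd": 1.5, "units": "degC"}
]
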