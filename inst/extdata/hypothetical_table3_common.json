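{
  "description": "Hypothetical common adverse event (1/10,000 per dose), whole population, relative incidence 3.0, Ontario-anchored throughput.",
  "design": {
    "relative_incidence": 3.0,
    "risk_days": 28,
    "observation_days": 180,
    "alpha": 0.05,
    "power": 0.90
  },
  "per_dose_risk": "1/10000",
  "stratum": "total",
  "throughput": {
    "mode": "anchored",
    "anchor_doses_per_day": 50000,
    "anchor_jurisdiction": "Ontario"
  },
  "rows": [
    ["Ontario"],
    ["Quebec"],
    ["British Columbia"],
    ["Alberta"],
    ["Manitoba"],
    ["Saskatchewan"],
    ["Nova Scotia"],
    ["New Brunswick"],
    ["Newfoundland and Labrador"],
    ["Prince Edward Island"],
    ["Ontario", "Quebec"],
    ["British Columbia", "Alberta", "Saskatchewan", "Manitoba", "Ontario"],
    ["Canada"]
  ],
  "labels": ["Ontario", "Quebec", "British Columbia", "Alberta", "Manitoba",
             "Saskatchewan", "Nova Scotia", "New Brunswick",
             "Newfoundland and Labrador", "Prince Edward Island",
             "ON/PQ", "BC/AB/SK/MB/ON", "Canada"],
  "national_aggregation": "summed"
}
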