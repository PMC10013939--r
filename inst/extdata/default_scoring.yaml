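# Default HBSR scoring configuration, version 1.
# Grades: low = 0 points, moderate = 1, high = 2; five factors, total 0-10.
smoking:
  daily: high
  occasional: moderate
  ex_smoker: moderate
  never: low
bmi:
  ge30: high
  b25_29_9: moderate
  lt25: low
exercise:
  ge4_per_week: low
  w2_3_per_week: low
  once_per_week: moderate
  m2_3_per_month: moderate
  rare_or_none: high
diet:
  adverse_salting: before_tasting
  veg_days_threshold: 6
alcohol:
  adverse_freq:
  - ge2_per_week
  - once_per_week
  units_threshold:
    female: 8
    male: 16
  units_comparison: '>'
composite_grades:
- low
- moderate
- high
high_cutoff: 6
missing_policy: require_complete
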