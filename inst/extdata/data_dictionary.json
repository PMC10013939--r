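{
  "id": {
    "type": "string",
    "description": "Opaque respondent identifier, unique within a cohort."
  },
  "group": {
    "type": "enum",
    "levels": ["patient", "control"],
    "description": "Study arm: ischemic-stroke patient or population-survey control."
  },
  "age": {
    "type": "integer",
    "unit": "years",
    "range": [18, 54],
    "description": "Age at questionnaire; records outside 18-54 are rejected."
  },
  "sex": {
    "type": "enum",
    "levels": ["male", "female"]
  },
  "education": {
    "type": "enum",
    "levels": ["basic", "secondary", "higher"]
  },
  "marital": {
    "type": "enum",
    "levels": ["married_cohabiting", "single", "divorced_widowed"]
  },
  "smoking": {
    "type": "enum",
    "levels": ["daily", "occasional", "ex_smoker", "never"],
    "missing_allowed": true,
    "description": "Ex-smoker: quit at least one year ago."
  },
  "bmi": {
    "type": "number",
    "unit": "kg/m2",
    "range_exclusive": [10, 80],
    "missing_allowed": true,
    "description": "Body-mass index; may instead be supplied as height_cm + weight_kg columns (reported bmi wins on conflict)."
  },
  "exercise": {
    "type": "enum",
    "levels": ["ge4_per_week", "w2_3_per_week", "once_per_week", "m2_3_per_month", "rare_or_none"],
    "missing_allowed": true,
    "description": "Physical exercise frequency."
  },
  "veg_days": {
    "type": "integer",
    "range": [0, 7],
    "missing_allowed": true,
    "description": "Days per week with vegetable consumption; may instead be supplied as a binary 'vegetables' column with levels ge6/lt6 (mapped to 6 and 0)."
  },
  "salting": {
    "type": "enum",
    "levels": ["before_tasting", "when_needed", "never"],
    "missing_allowed": true,
    "description": "Habit of adding salt to ready-made meals."
  },
  "alcohol_freq": {
    "type": "enum",
    "levels": ["ge2_per_week", "once_per_week", "m2_3_per_month", "few_per_year", "none"],
    "missing_allowed": true,
    "description": "Frequency of alcohol use."
  },
  "alcohol_units_7d": {
    "type": "number",
    "unit": "standard drink units",
    "range": [0, null],
    "missing_allowed": true,
    "description": "Standard drink units consumed in the last 7 days; 'none' drinkers with positive units trigger a consistency warning."
  }
}
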