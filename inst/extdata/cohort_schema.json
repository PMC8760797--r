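{
  "description": "Column contract for the four cohort CSV tables; timestamps are ISO-8601 (YYYY-MM-DDTHH:MM:SS), timezone-naive local time.",
  "tables": {
    "encounters.csv": {
      "required": ["encounter_id", "pdms_admission", "his_discharge"],
      "optional": ["first_vital", "last_vital", "referral_group", "icu_death", "start", "end"],
      "referral_group": ["neurosurgical", "non_neurosurgical", "unknown"]
    },
    "observations.csv": {
      "required": ["encounter_id", "time", "variable", "value"],
      "variables": ["temperature", "heart_rate", "resp_rate", "paco2", "wbc",
                    "band_fraction", "pao2_fio2", "platelets", "bilirubin", "map",
                    "norepinephrine", "epinephrine", "dopamine", "dobutamine",
                    "ventilated", "gcs", "creatinine", "urine_output_24h"]
    },
    "orders.csv": {
      "required": ["encounter_id", "time", "kind"],
      "kind": ["antibiotic_administration", "body_fluid_culture"]
    },
    "gtsq.csv": {
      "required": ["encounter_id", "rating_time", "working_diagnosis", "edited"],
      "optional": ["suspicion_of_infection"],
      "working_diagnosis": ["neither", "SIRS", "sepsis", "severe_sepsis", "septic_shock"]
    }
  }
}
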