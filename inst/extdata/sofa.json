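{
  "description": "Default SOFA subscore cut-offs (original six-system table); respiration scores 3-4 require ventilatory support, with ventilation status unknown the respiration subscore is capped at 2.",
  "pao2_fio2": [400, 300, 200, 100],
  "platelets": [150, 100, 50, 20],
  "bilirubin": [1.2, 2.0, 6.0, 12.0],
  "map_low": 70,
  "dopamine": [5, 15],
  "epi_norepi": 0.1,
  "gcs": [15, 13, 10, 6],
  "creatinine": [1.2, 2.0, 3.5, 5.0],
  "urine": [500, 200]
}
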