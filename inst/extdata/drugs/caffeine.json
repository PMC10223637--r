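{
  "name": "caffeine",
  "mw": 194.2,
  "logp": -0.07,
  "pka": [
    {
      "kind": "base",
      "pka": 0.8
    }
  ],
  "hbd": 0,
  "hba": 3,
  "psa": 58.44,
  "fu_plasma": 0.7,
  "pk": {
    "cl": 5,
    "vc": 36,
    "peripherals": [],
    "ka": 3,
    "f": 1,
    "tlag": 0
  },
  "regimen": {
    "dose_mg": 100,
    "interval_h": 8,
    "n_doses": 15,
    "route": "oral"
  },
  "therapeutic_dose_mg_kg_day": 5,
  "published": {
    "clsec_ml_h": 824.02,
    "clre_ml_h": 603.21,
    "mp_ratio": 0.95
  },
  "effective": {
    "logp": -0.07,
    "logd74": -0
  },
  "provenance": {
    "physchem": "published",
    "clearances": "published",
    "effective": "backcalculated",
    "pk": "user",
    "regimen": "user"
  },
  "notes": "Maternal PK parameters are literature-plausible placeholders, not fitted values. Effective inputs are back-calculated from the published clearances."
}
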