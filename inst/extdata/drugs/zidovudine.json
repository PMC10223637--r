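{
  "name": "zidovudine",
  "mw": 267.24,
  "logp": 0.05,
  "pka": [
    {
      "kind": "acid",
      "pka": 9.7
    }
  ],
  "hbd": 2,
  "hba": 6,
  "psa": 108.3,
  "fu_plasma": 0.8,
  "pk": {
    "cl": 96,
    "vc": 100,
    "peripherals": [],
    "ka": 2,
    "f": 0.64,
    "tlag": 0
  },
  "regimen": {
    "dose_mg": 300,
    "interval_h": 12,
    "n_doses": 14,
    "route": "oral"
  },
  "therapeutic_dose_mg_kg_day": 24,
  "published": {
    "clsec_ml_h": 431.04,
    "clre_ml_h": 345.1,
    "mp_ratio": 1.1
  },
  "effective": {
    "logp": 0.05,
    "logd74": 0.0022
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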