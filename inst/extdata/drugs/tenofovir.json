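{
  "name": "tenofovir",
  "mw": 287.21,
  "logp": 1.87,
  "pka": [
    {
      "kind": "acid",
      "pka": 1.35
    },
    {
      "kind": "acid",
      "pka": 6.7
    },
    {
      "kind": "base",
      "pka": 3.8
    }
  ],
  "hbd": 3,
  "hba": 8,
  "psa": 136.38,
  "fu_plasma": 0.993,
  "pk": {
    "cl": 38,
    "vc": 80,
    "peripherals": [
      {
        "v": 160,
        "q": 15
      }
    ],
    "ka": 1,
    "f": 0.25,
    "tlag": 0.25
  },
  "regimen": {
    "dose_mg": 300,
    "interval_h": 24,
    "n_doses": 10,
    "route": "oral"
  },
  "therapeutic_dose_mg_kg_day": 6.5,
  "published": {
    "clsec_ml_h": 51.96,
    "clre_ml_h": 129,
    "mp_ratio": 0.4
  },
  "effective": {
    "logp": -1.6001,
    "logd74": 3.6792
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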