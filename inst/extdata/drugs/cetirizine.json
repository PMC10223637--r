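{
  "name": "cetirizine",
  "mw": 388.9,
  "logp": 1.5,
  "pka": [
    {
      "kind": "acid",
      "pka": 2.9
    },
    {
      "kind": "base",
      "pka": 8
    },
    {
      "kind": "base",
      "pka": 2.2
    }
  ],
  "hbd": 1,
  "hba": 5,
  "psa": 53,
  "fu_plasma": 0.07,
  "pk": {
    "cl": 3.2,
    "vc": 30,
    "peripherals": [],
    "ka": 1.2,
    "f": 0.93,
    "tlag": 0.25
  },
  "regimen": {
    "dose_mg": 10,
    "interval_h": 24,
    "n_doses": 10,
    "route": "oral"
  },
  "therapeutic_dose_mg_kg_day": 0.5,
  "published": {
    "clsec_ml_h": 3031.27,
    "clre_ml_h": 1922.74,
    "mp_ratio": 0.12
  },
  "effective": {
    "logp": 3.48,
    "logd74": 3.24
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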