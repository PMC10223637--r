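{
  "name": "amoxicillin",
  "mw": 365.4,
  "logp": 0.87,
  "pka": [
    {
      "kind": "acid",
      "pka": 3.23
    },
    {
      "kind": "base",
      "pka": 7.43
    }
  ],
  "hbd": 4,
  "hba": 7,
  "psa": 158,
  "fu_plasma": 0.85,
  "pk": {
    "cl": 18,
    "vc": 27,
    "peripherals": [],
    "ka": 1.5,
    "f": 0.9,
    "tlag": 0.25
  },
  "regimen": {
    "dose_mg": 1000,
    "interval_h": 8,
    "n_doses": 15,
    "route": "oral"
  },
  "therapeutic_dose_mg_kg_day": 50,
  "published": {
    "clsec_ml_h": 46.9,
    "clre_ml_h": 263.47,
    "mp_ratio": 0.15
  },
  "effective": {
    "logp": 0.87,
    "logd74": 4.1199
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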