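{
  "name": "valproic_acid",
  "mw": 144.21,
  "logp": 2.75,
  "pka": [
    {
      "kind": "acid",
      "pka": 4.8
    }
  ],
  "hbd": 1,
  "hba": 2,
  "psa": 37.3,
  "fu_plasma": 0.14,
  "pk": {
    "cl": 0.5,
    "vc": 11,
    "peripherals": [],
    "ka": 1.5,
    "f": 1,
    "tlag": 0
  },
  "regimen": {
    "dose_mg": 2100,
    "interval_h": 24,
    "n_doses": 10,
    "route": "oral"
  },
  "therapeutic_dose_mg_kg_day": 40,
  "published": {
    "clsec_ml_h": 248.39,
    "clre_ml_h": 1423.15,
    "mp_ratio": 0.03
  },
  "effective": {
    "logp": 2.75,
    "logd74": 2.4555
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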