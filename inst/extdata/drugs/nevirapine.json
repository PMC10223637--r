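{
  "name": "nevirapine",
  "mw": 266.3,
  "logp": 1.93,
  "pka": [
    {
      "kind": "base",
      "pka": 2.8
    }
  ],
  "hbd": 1,
  "hba": 4,
  "psa": 58.1,
  "fu_plasma": 0.4,
  "pk": {
    "cl": 1.9,
    "vc": 75,
    "peripherals": [],
    "ka": 1,
    "f": 0.93,
    "tlag": 0
  },
  "regimen": {
    "dose_mg": 200,
    "interval_h": 12,
    "n_doses": 30,
    "route": "oral"
  },
  "therapeutic_dose_mg_kg_day": 12,
  "published": {
    "clsec_ml_h": 2413.86,
    "clre_ml_h": 1015.01,
    "mp_ratio": 2.68
  },
  "effective": {
    "logp": 1.93,
    "logd74": 0.0001
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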