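{
  "name": "levetiracetam",
  "mw": 170.21,
  "logp": -0.6,
  "pka": [],
  "hbd": 1,
  "hba": 2,
  "psa": 63.4,
  "fu_plasma": 0.9,
  "pk": {
    "cl": 3.9,
    "vc": 42,
    "peripherals": [],
    "ka": 2,
    "f": 1,
    "tlag": 0
  },
  "regimen": {
    "dose_mg": 1500,
    "interval_h": 12,
    "n_doses": 10,
    "route": "oral"
  },
  "therapeutic_dose_mg_kg_day": 40,
  "published": {
    "clsec_ml_h": 445.38,
    "clre_ml_h": 357.77,
    "mp_ratio": 1.11
  },
  "effective": {
    "logp": -0.6,
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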