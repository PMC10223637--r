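{
  "name": "sertraline",
  "mw": 306,
  "logp": 5.5,
  "pka": [
    {
      "kind": "base",
      "pka": 9.43
    }
  ],
  "hbd": 1,
  "hba": 1,
  "psa": 12.03,
  "fu_plasma": 0.023,
  "pk": {
    "cl": 96,
    "vc": 400,
    "peripherals": [
      {
        "v": 800,
        "q": 60
      }
    ],
    "ka": 0.5,
    "f": 0.44,
    "tlag": 0.5
  },
  "regimen": {
    "dose_mg": 50,
    "interval_h": 24,
    "n_doses": 20,
    "route": "oral"
  },
  "published": {
    "clsec_ml_h": 8925.7,
    "clre_ml_h": 3597.49,
    "mp_ratio": 1.62
  },
  "effective": {
    "logp": 5,
    "logd74": 1.9898
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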