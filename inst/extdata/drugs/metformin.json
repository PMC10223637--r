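{
  "name": "metformin",
  "mw": 129.16,
  "logp": -1.43,
  "pka": [
    {
      "kind": "base",
      "pka": 2.8
    },
    {
      "kind": "acid",
      "pka": 11.5
    }
  ],
  "hbd": 3,
  "hba": 1,
  "psa": 91.5,
  "fu_plasma": 1,
  "pk": {
    "cl": 42,
    "vc": 100,
    "peripherals": [
      {
        "v": 200,
        "q": 20
      }
    ],
    "ka": 0.6,
    "f": 0.55,
    "tlag": 0.5
  },
  "regimen": {
    "dose_mg": 500,
    "interval_h": 12,
    "n_doses": 14,
    "route": "oral"
  },
  "published": {
    "clsec_ml_h": 21.73,
    "clre_ml_h": 138.37,
    "mp_ratio": 0.16
  },
  "effective": {
    "logp": -1.4299,
    "logd74": 2.9671
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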