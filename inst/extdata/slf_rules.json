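{
  "comment": "Boolean ROI recipes for virtual dissection of the SLF branches. Every include ('AND') ROI must be visited; no exclude ('NOT') ROI may be touched. The neonate protocol differs from the adult protocol only in the SLF II include ROIs, where the posterior middle-frontal ROI replaces the parietal ROI.",
  "adult": [
    {"bundle": "SLF I",   "hemisphere": "L", "include": ["PaL", "SFgL"],      "exclude": ["TeL", "Midsag"]},
    {"bundle": "SLF II",  "hemisphere": "L", "include": ["PaL", "MFgL"],      "exclude": ["TeL", "Midsag"]},
    {"bundle": "SLF III", "hemisphere": "L", "include": ["PaL", "PrgL"],      "exclude": ["TeL", "Midsag"]},
    {"bundle": "SLF I",   "hemisphere": "R", "include": ["PaR", "SFgR"],      "exclude": ["TeR", "Midsag"]},
    {"bundle": "SLF II",  "hemisphere": "R", "include": ["PaR", "MFgR"],      "exclude": ["TeR", "Midsag"]},
    {"bundle": "SLF III", "hemisphere": "R", "include": ["PaR", "PrgR"],      "exclude": ["TeR", "Midsag"]}
  ],
  "neonate": [
    {"bundle": "SLF I",   "hemisphere": "L", "include": ["PaL", "SFgL"],      "exclude": ["TeL", "Midsag"]},
    {"bundle": "SLF II",  "hemisphere": "L", "include": ["MFgL-P", "MFgL"],   "exclude": ["TeL", "Midsag"]},
    {"bundle": "SLF III", "hemisphere": "L", "include": ["PaL", "PrgL"],      "exclude": ["TeL", "Midsag"]},
    {"bundle": "SLF I",   "hemisphere": "R", "include": ["PaR", "SFgR"],      "exclude": ["TeR", "Midsag"]},
    {"bundle": "SLF II",  "hemisphere": "R", "include": ["MFgR-P", "MFgR"],   "exclude": ["TeR", "Midsag"]},
    {"bundle": "SLF III", "hemisphere": "R", "include": ["PaR", "PrgR"],      "exclude": ["TeR", "Midsag"]}
  ]
}
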