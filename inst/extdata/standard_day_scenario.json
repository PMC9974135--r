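{
  "t_start": 0,
  "t_end": 1440,
  "meals": [
    {"time": "07:00", "cho_g": 40, "label": "breakfast"},
    {"time": "13:00", "cho_g": 60, "label": "lunch"},
    {"time": "19:00", "cho_g": 50, "label": "dinner"}
  ],
  "boluses": [
    {"time": "07:00", "dose_U": 4, "label": "breakfast"},
    {"time": "13:00", "dose_U": 6, "label": "lunch"},
    {"time": "19:00", "dose_U": 5, "label": "dinner"}
  ],
  "basal": 0.8,
  "activity": {
    "bouts": [
      {"start": "15:30", "duration": 60, "intensity": 60}
    ]
  }
}
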