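{
  "codes": {
    "0": "background",
    "1": "tumor_epithelium",
    "2": "tumor_stroma",
    "3": "necrosis",
    "4": "mucin",
    "5": "smooth_muscle",
    "6": "mucosa",
    "7": "submucosa",
    "8": "adventitial",
    "9": "lymphocytic",
    "10": "bleeding",
    "255": "excluded"
  },
  "roles": {
    "background": 0,
    "tumor_epithelium": 1,
    "tumor_stroma": 2,
    "necrosis": 3,
    "mucin": 4,
    "excluded": 255
  },
  "mpp": 1
}
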