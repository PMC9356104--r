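{
  "attractors": {
    "blue_LIF_CH_PD":  {"LIF": 1, "CH": 1, "PD": 1, "Stat3": 1, "MEKERK": 0, "Tcf3": 0,
                        "Gbx2": 1, "Klf4": 1, "Klf2": 1, "Sall4": 1, "Oct4": 1,
                        "Sox2": 1, "Nanog": 1, "Esrrb": 1, "Tfcp2l1": 1},
    "orange_LIF_CH":   {"LIF": 1, "CH": 1, "PD": 0, "Stat3": 1, "MEKERK": 1, "Tcf3": 0,
                        "Gbx2": 1, "Klf4": 1, "Klf2": 1, "Sall4": 1, "Oct4": 1,
                        "Sox2": 1, "Nanog": 1, "Esrrb": 1, "Tfcp2l1": 1},
    "green_CH_PD":     {"LIF": 0, "CH": 1, "PD": 1, "Stat3": 0, "MEKERK": 0, "Tcf3": 0,
                        "Gbx2": 0, "Klf4": 0, "Klf2": 1, "Sall4": 1, "Oct4": 1,
                        "Sox2": 1, "Nanog": 1, "Esrrb": 1, "Tfcp2l1": 1},
    "red_LIF_PD":      {"LIF": 1, "CH": 0, "PD": 1, "Stat3": 1, "MEKERK": 0, "Tcf3": 1,
                        "Gbx2": 1, "Klf4": 1, "Klf2": 1, "Sall4": 1, "Oct4": 1,
                        "Sox2": 1, "Nanog": 1, "Esrrb": 1, "Tfcp2l1": 1}
  },
  "media": ["LIF", "CH", "PD"]
}
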