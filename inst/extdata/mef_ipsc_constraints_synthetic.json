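{
  "attractors": {
    "MEF":      {"LIF": 1, "Stat3": 1, "Klf4": 0, "Klf2": 0, "Esrrb": 0, "Tcf3": 0,
                 "MEKERK": 1, "Gbx2": 0, "Sox2": 0, "Oct4": 0, "Tbx3": 0,
                 "Tfcp2l1": 0, "Sall4": 0, "Nanog": 0},
    "NG_block": {"LIF": 1, "Stat3": 1, "Klf4": 1, "Klf2": 1, "Esrrb": 1, "Tcf3": 0,
                 "MEKERK": 0, "Gbx2": 0, "Sox2": 0, "Oct4": 1, "Tbx3": 0,
                 "Tfcp2l1": 1, "Sall4": 1, "Nanog": 0},
    "iPSC":     {"LIF": 1, "Stat3": 1, "Klf4": 1, "Klf2": 1, "Esrrb": 1, "Tcf3": 0,
                 "MEKERK": 0, "Gbx2": 1, "Sox2": 1, "Oct4": 1, "Tbx3": 1,
                 "Tfcp2l1": 1, "Sall4": 1, "Nanog": 1}
  },
  "media": ["LIF"]
}
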