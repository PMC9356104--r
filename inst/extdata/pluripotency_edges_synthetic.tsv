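# Synthetic reconstruction of the 15-node network governing maintenance of
# naive pluripotency (12 transcription factors + 3 medium components LIF,
# CH, PD). The published wiring is shown only as a figure; this edge list
# follows the textual descriptions of the circuit (LIF -> Stat3; PD inhibits
# MEKERK; CH and MEKERK both repress Tcf3; MEKERK represses Nanog; Oct4
# receives Sox2, Klf2 and Esrrb; Tfcp2l1 receives Stat3, Esrrb, Klf4,
# repressive Oct4 and repressive Tcf3) and reproduces the published
# in-degree profile: with all six operators the network admits exactly
# 28179280429056 operator configurations.
!genes: LIF CH PD Stat3 MEKERK Tcf3 Gbx2 Klf4 Klf2 Sall4 Oct4 Sox2 Nanog Esrrb Tfcp2l1
!media: LIF CH PD
source	target	sign
LIF	Stat3	activate
PD	MEKERK	repress
CH	Tcf3	repress
MEKERK	Tcf3	repress
MEKERK	Nanog	repress
Oct4	Nanog	activate
Sox2	Nanog	activate
Nanog	Sox2	activate
Sox2	Oct4	activate
Klf2	Oct4	activate
Esrrb	Oct4	activate
Stat3	Tfcp2l1	activate
Esrrb	Tfcp2l1	activate
Klf4	Tfcp2l1	activate
Oct4	Tfcp2l1	repress
Tcf3	Tfcp2l1	repress
Nanog	Esrrb	activate
Tfcp2l1	Esrrb	activate
Tcf3	Esrrb	repress
Tfcp2l1	Sall4	activate
Esrrb	Klf2	activate
Klf4	Klf2	activate
Stat3	Klf4	activate
Gbx2	Klf4	activate
Stat3	Gbx2	activate
Sox2	Gbx2	activate
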