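# Synthetic 5-gene toy network (A..E). The published toy model is shown only
# as a figure; this edge list is a figure-style reconstruction built so that
# the two toy constraint states (10110 and 11101, i.e. indices 22 and 29)
# are attainable as attractors under the {AND_HI, OR_HI} operator pair.
# Gene C receives input from B and E, as in the original toy model.
!genes: A B C D E
source	target	sign
D	A	activate
B	A	repress
A	B	repress
D	B	repress
B	C	activate
E	C	activate
A	D	activate
B	D	repress
C	E	activate
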