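# synthetic test morphology (not a reconstruction): lumped soma,
# one bifurcating dendrite and one unbranched dendrite; units um
1 1 0 0 0 10 -1
2 1 0 18 0 8 1
3 3 30 0 0 1.5 1
4 3 80 0 0 1.2 3
5 3 140 40 0 1.0 4
6 3 140 -40 0 1.0 4
7 3 200 -80 0 0.8 6
8 3 0 -60 0 1.0 1
9 3 0 -140 0 1.0 8
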