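# Synthetic stand-in for the KEGG insulin-resistance pathway topology:
# an undirected, connected graph with the pathway's published counts
# (26 nodes, 37 edges), nodes labelled X1..X26, including edge X4-X10.
# The exact KEGG wiring is not reproduced here; simulation results using
# this topology draw effecting nodes/edges at random, so conclusions do
# not depend on the specific edge set.
X1	X2
X2	X3
X3	X4
X4	X5
X4	X10
X5	X6
X6	X7
X7	X8
X8	X9
X9	X10
X10	X11
X11	X12
X12	X13
X13	X14
X14	X15
X15	X16
X16	X17
X17	X18
X18	X19
X19	X20
X20	X21
X21	X22
X22	X23
X23	X24
X24	X25
X25	X26
X2	X7
X3	X9
X5	X12
X6	X13
X8	X15
X11	X18
X14	X21
X16	X23
X17	X24
X19	X26
X20	X25
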