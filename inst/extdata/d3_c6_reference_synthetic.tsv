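# Compact synthetic C6 reference set for the pairwise dispersion model.
# One row per (element, reference coordination number); c6 is the
# homonuclear reference coefficient in hartree*bohr^6, anchored at
# free-atom-limit magnitudes from the dispersion literature and decreasing
# with coordination. Heteronuclear reference values are formed as geometric
# means of these anchors. See d3_data_manifest.md.
elem	cn	c6
H	0.000	7.59
H	0.912	3.09
C	0.000	49.11
C	0.987	43.25
C	1.998	29.36
C	2.999	25.78
C	3.984	18.21
N	0.000	25.27
N	0.994	19.67
N	2.014	15.58
N	2.990	12.82
O	0.000	15.51
O	0.993	12.05
O	1.989	10.37
F	0.000	9.69
F	0.998	7.13
P	0.000	185.33
P	0.998	168.07
P	2.990	150.24
S	0.000	134.01
S	0.995	119.87
S	1.990	104.70
Cl	0.000	94.60
Cl	0.997	90.40
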