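# Element-wise sqrt expectation-value ratios <r^4>/<r^2> (dimensionless, q)
# entering C8 = 3 C6 sqrt(qA qB). Compact synthetic set; see
# d3_data_manifest.md.
elem	q
H	2.0073
C	3.1049
N	2.7118
O	2.5936
F	2.3883
P	4.2973
S	4.0411
Cl	3.7293
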