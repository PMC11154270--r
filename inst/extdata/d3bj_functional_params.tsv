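# Global scalings (s6, s8) and Becke-Johnson damping constants (a1
# dimensionless, a2 bohr) per exchange-correlation functional, following
# the standard BJ-damping fits where available. Rows with source=nominal
# are placeholders for functionals conventionally parameterized with zero
# damping; override via the `file` argument of d3_functional_params().
functional	s6	s8	a1	a2	source
BLYP	1.0	2.6996	0.4298	4.2359	fitted
TPSS	1.0	1.9435	0.4535	4.4752	fitted
B97	1.0	2.2609	0.5545	3.2297	fitted
wB97X	1.0	1.0000	0.0000	5.5000	nominal
B3LYP	1.0	1.9889	0.3981	4.4211	fitted
M062X	1.0	0.0000	0.0000	5.9581	nominal
PW6B95	1.0	0.7257	0.2076	6.3750	fitted
B2PLYP	0.64	0.9147	0.3065	5.0570	fitted
PWPB95	0.82	0.2904	0.0000	7.3141	fitted
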