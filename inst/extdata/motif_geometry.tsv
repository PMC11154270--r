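# Geometric descriptors for the 49-motif library: interaction mode, parent
# PDB entry, interacting pair (ligand three-letter ID ... residue ID),
# plane angle for pi-pi motifs (deg), D-H...A angles for H-bond motifs
# (deg; dual H-bonds except motif 40, hence two columns), and distances
# (Angstrom): closest C/N/O contact, or the two donor-acceptor distances
# for H-bond motifs. Empty fields are NA.
motif_no	mode	pdb_id	pair	angle1	angle2	dist1	dist2
1	CH-pi	1H1Q	2A6...A31	NA	NA	3.32	NA
2	CH-pi	4BDB	ODO...L354	NA	NA	3.93	NA
3	CH-pi	2BTS	U32...I10	NA	NA	3.55	NA
4	CH-pi	2XIY	XIY...L174	NA	NA	3.57	NA
5	CH-pi	1UU9	BI3...L88	NA	NA	3.81	NA
6	CH-pi	2IO6	330...I374	NA	NA	4.41	NA
7	CH-pi	4GUE	QCT...L147	NA	NA	3.61	NA
8	CH-pi	3OOG	YTP...A70	NA	NA	3.34	NA
9	CH-pi	4FKO	20K...I10	NA	NA	3.72	NA
10	CH-pi	3QL8	X01...L134	NA	NA	3.23	NA
11	CH-pi	4RC2	3O8...L174	NA	NA	3.43	NA
12	CH-pi	4RC3	3OA...A56	NA	NA	3.27	NA
13	CH-pi	3QX4	X4B...L134	NA	NA	3.61	NA
14	pi-pi	2V7O	DRN...F90	89.64	NA	3.77	NA
15	pi-pi	3I4B	Z48...Y134	6.8	NA	4.31	NA
16	pi-pi	4DGO	0JW...F113	43.85	NA	3.55	NA
17	pi-pi	3QQF	X07...F82	70.14	NA	3.76	NA
18	pi-pi	3B2T	M33...Y566	10.09	NA	3.83	NA
19	pi-pi	3R6X	X84...F82	74.54	NA	3.71	NA
20	pi-pi	4WG4	UWB...Y131	5.57	NA	4.08	NA
21	pi-pi	1PXN	CK6...F82	16.8	NA	3.62	NA
22	pi-pi	3ROY	22Z...F82	68.31	NA	3.75	NA
23	pi-pi	2C6O	4SP...F82	20.3	NA	4.01	NA
24	pi-pi	3RAK	03Z...F82	41.29	NA	3.81	NA
25	pi-pi	4EL9	AFE...F79	19.17	NA	3.48	NA
26	cation-pi	1PXL	CK4...K33	NA	NA	4.62	NA
27	cation-pi	1FGI	SU1...K514	NA	NA	5.15	NA
28	cation-pi	1M2Q	MNX...K68	NA	NA	4.21	NA
29	cation-pi	2VGP	AD6...K180	NA	NA	5.06	NA
30	cation-pi	3OWP	2SB...K72	NA	NA	3.59	NA
31	cation-pi	3SQQ	99Z...K33	NA	NA	5.12	NA
32	cation-pi	3RJC	06Z...K33	NA	NA	4.77	NA
33	cation-pi	3QTW	X3A...K89	NA	NA	3.51	NA
34	H-bond	3SW4	18K...L83	158.59	166.51	2.88	2.94
35	H-bond	3ZLY	YSO...M146	153.12	164.48	2.97	3.26
36	H-bond	3RZB	02Z...L83	143.48	162.20	2.96	3.06
37	H-bond	3RPY	27Z...L83	141.82	167.13	2.89	3.24
38	H-bond	3R28	XA0...L83	155.87	134.34	2.88	2.98
39	H-bond	3QZI	X72...L83	132.02	148.51	2.98	2.98
40	H-bond	3SXF	BK5...Y131	161.45	NA	3.14	NA
41	H-bond	2R3P	3SC...L83	141.41	168.79	2.82	3.35
42	salt-bridge	3MA3	01I...K67	NA	NA	3.38	NA
43	salt-bridge	4L9I	8PR...D271	NA	NA	3.96	NA
44	salt-bridge	1NVQ	UCN...E91	NA	NA	3.48	NA
45	salt-bridge	4JIK	1KO...D148	NA	NA	3.22	NA
46	salt-bridge	1BX6	BA1...E127	NA	NA	5.05	NA
47	salt-bridge	4WG4	UWB...E135	NA	NA	4.16	NA
48	salt-bridge	4MTA	2D2...K67	NA	NA	3.67	NA
49	salt-bridge	1E9H	INR...K33	NA	NA	3.65	NA
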