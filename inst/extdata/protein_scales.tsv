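aa	hbond	vdw	helix
A	0.10	0.31	1.42
R	0.95	0.84	0.98
N	0.78	0.48	0.67
D	0.82	0.43	1.01
C	0.25	0.45	0.70
Q	0.76	0.62	1.11
E	0.84	0.58	1.51
G	0.12	0.00	0.57
H	0.70	0.66	1.00
I	0.05	0.76	1.08
L	0.05	0.76	1.21
K	0.90	0.71	1.16
M	0.15	0.74	1.45
F	0.18	0.88	1.13
P	0.20	0.46	0.57
S	0.65	0.28	0.77
T	0.60	0.44	0.83
W	0.55	1.00	1.08
Y	0.58	0.91	0.69
V	0.05	0.62	1.06
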