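stack	type	dG
AA	WC	-0.93
AC	WC	-2.24
AG	WC	-2.08
AT	WC	-1.10
CA	WC	-2.11
CC	WC	-3.26
CG	WC	-2.36
CT	WC	-2.08
GA	WC	-2.35
GC	WC	-3.42
GG	WC	-3.26
GT	WC	-2.24
TA	WC	-1.33
TC	WC	-2.35
TG	WC	-2.11
TT	WC	-0.93
GU_one	GU	-1.30
GU_two	GU	-0.50
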