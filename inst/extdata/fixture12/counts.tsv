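feature_id	T_1	E_1	DD_1
PC1	16	16	18
PC2	66	66	68
PC3	5	5	5
SHORT1	16	16	18
MONO1	16	16	18
LOW1	1	1	3
EDGE_LEN200	16	16	18
EDGE_CNT10	3	3	4
KEEP1	3	3	5
KEEP2	40	40	40
KEEP3	20	20	20
KEEP4	10	10	10
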