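sample_id	tissue	replicate
T_1	T	1
E_1	E	1
DD_1	DD	1
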