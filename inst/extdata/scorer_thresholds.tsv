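scorer	threshold	coding_if_greater	mean_coding	mean_noncoding
orf_length	2.77500000e+02	TRUE	6.864654e+02	7.935480e+01
orf_coverage	3.42365098e-01	TRUE	6.523414e-01	1.281393e-01
fickett	5.51550000e-01	TRUE	7.097711e-01	4.513932e-01
hexamer	1.64946576e-02	TRUE	2.715697e-01	-2.193317e-01
kmer_spectrum	4.91193538e-01	TRUE	9.995941e-01	4.059523e-04
triplet_frame	1.95966788e-02	TRUE	2.768779e-01	-1.903181e-01
stop_density	-4.22937211e-02	FALSE	-6.626490e-02	-1.697717e-02
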