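chr1	lncLink	exon	1000	1249	.	+	.	gene_id "G_PC1"; transcript_id "PC1"; gene_biotype "protein_coding";
chr1	lncLink	exon	1549	1798	.	+	.	gene_id "G_PC1"; transcript_id "PC1"; gene_biotype "protein_coding";
chr1	lncLink	exon	7098	7365	.	+	.	gene_id "G_PC2"; transcript_id "PC2"; gene_biotype "protein_coding";
chr1	lncLink	exon	7665	7930	.	+	.	gene_id "G_PC2"; transcript_id "PC2"; gene_biotype "protein_coding";
chr1	lncLink	exon	8230	8495	.	+	.	gene_id "G_PC2"; transcript_id "PC2"; gene_biotype "protein_coding";
chr1	lncLink	exon	13795	13944	.	+	.	gene_id "G_PC3"; transcript_id "PC3"; gene_biotype "protein_coding";
chr1	lncLink	exon	14244	14393	.	+	.	gene_id "G_PC3"; transcript_id "PC3"; gene_biotype "protein_coding";
chr1	lncLink	exon	19693	19742	.	+	.	gene_id "G_SHORT1"; transcript_id "SHORT1"; gene_biotype "other";
chr1	lncLink	exon	20042	20091	.	+	.	gene_id "G_SHORT1"; transcript_id "SHORT1"; gene_biotype "other";
chr1	lncLink	exon	20391	20440	.	+	.	gene_id "G_SHORT1"; transcript_id "SHORT1"; gene_biotype "other";
chr1	lncLink	exon	25740	26239	.	+	.	gene_id "G_MONO1"; transcript_id "MONO1"; gene_biotype "other";
chr1	lncLink	exon	31539	31788	.	+	.	gene_id "G_LOW1"; transcript_id "LOW1"; gene_biotype "other";
chr1	lncLink	exon	32088	32337	.	+	.	gene_id "G_LOW1"; transcript_id "LOW1"; gene_biotype "other";
chr1	lncLink	exon	37637	37736	.	+	.	gene_id "G_EDGE_LEN200"; transcript_id "EDGE_LEN200"; gene_biotype "other";
chr1	lncLink	exon	38036	38135	.	+	.	gene_id "G_EDGE_LEN200"; transcript_id "EDGE_LEN200"; gene_biotype "other";
chr1	lncLink	exon	43435	43684	.	+	.	gene_id "G_EDGE_CNT10"; transcript_id "EDGE_CNT10"; gene_biotype "other";
chr1	lncLink	exon	43984	44233	.	+	.	gene_id "G_EDGE_CNT10"; transcript_id "EDGE_CNT10"; gene_biotype "other";
chr1	lncLink	exon	49533	49633	.	+	.	gene_id "G_KEEP1"; transcript_id "KEEP1"; gene_biotype "other";
chr1	lncLink	exon	49933	50032	.	+	.	gene_id "G_KEEP1"; transcript_id "KEEP1"; gene_biotype "other";
chr1	lncLink	exon	55332	55499	.	+	.	gene_id "G_KEEP2"; transcript_id "KEEP2"; gene_biotype "other";
chr1	lncLink	exon	55799	55964	.	+	.	gene_id "G_KEEP2"; transcript_id "KEEP2"; gene_biotype "other";
chr1	lncLink	exon	56264	56429	.	+	.	gene_id "G_KEEP2"; transcript_id "KEEP2"; gene_biotype "other";
chr1	lncLink	exon	61729	61903	.	+	.	gene_id "G_KEEP3"; transcript_id "KEEP3"; gene_biotype "other";
chr1	lncLink	exon	62203	62377	.	+	.	gene_id "G_KEEP3"; transcript_id "KEEP3"; gene_biotype "other";
chr1	lncLink	exon	62677	62851	.	+	.	gene_id "G_KEEP3"; transcript_id "KEEP3"; gene_biotype "other";
chr1	lncLink	exon	63151	63325	.	+	.	gene_id "G_KEEP3"; transcript_id "KEEP3"; gene_biotype "other";
chr1	lncLink	exon	68625	68799	.	+	.	gene_id "G_KEEP4"; transcript_id "KEEP4"; gene_biotype "other";
chr1	lncLink	exon	69099	69273	.	+	.	gene_id "G_KEEP4"; transcript_id "KEEP4"; gene_biotype "other";
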