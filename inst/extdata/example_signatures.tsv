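class	gene_id	sign
S1	mRNA_0101	1
S1	mRNA_0102	-1
S1	mRNA_0103	1
S1	mRNA_0104	-1
S2	mRNA_0105	1
S2	mRNA_0106	1
S2	mRNA_0107	-1
S2	mRNA_0108	-1
S3	mRNA_0109	1
S3	mRNA_0110	-1
S3	mRNA_0111	-1
S3	mRNA_0112	1
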