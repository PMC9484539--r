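synthetic_pathway_A	synthetic example set	mRNA_0001	mRNA_0002	mRNA_0003	mRNA_0004	mRNA_0005	mRNA_0006
synthetic_pathway_B	synthetic example set	mRNA_0010	mRNA_0011	mRNA_0012	mRNA_0013	mRNA_0014
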