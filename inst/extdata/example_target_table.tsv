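mirna_id	target_id	evidence	source
miRNA_0001	mRNA_0001	validated	synthetic_db
miRNA_0002	mRNA_0001	predicted	synthetic_db
miRNA_0002	mRNA_0002	validated	synthetic_db
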