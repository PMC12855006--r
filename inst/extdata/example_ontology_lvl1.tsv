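feature_id	term_id
rna_f0001	t01
rna_f0002	t02
rna_f0003	t01
rna_f0004	t02
rna_f0005	t01
rna_f0006	t02
rna_f0007	t01
rna_f0008	t02
rna_f0009	t01
rna_f0010	t02
rna_f0011	t01
rna_f0012	t02
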