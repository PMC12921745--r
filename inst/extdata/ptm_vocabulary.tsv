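source_name	ptm_name	residue	mass_delta
Phosphoserine	phospho	S	79.966331
Phosphothreonine	phospho	T	79.966331
Phosphotyrosine	phospho	Y	79.966331
Phosphorylation	phospho		79.966331
N-acetylalanine	acetyl	A	42.010565
N-acetylmethionine	acetyl	M	42.010565
N-acetylserine	acetyl	S	42.010565
N-acetylthreonine	acetyl	T	42.010565
N6-acetyllysine	acetyl	K	42.010565
Acetylation	acetyl		42.010565
Omega-N-methylarginine	methyl	R	14.01565
N6-methyllysine	methyl	K	14.01565
Methylation	methyl		14.01565
Asymmetric dimethylarginine	dimethyl	R	28.0313
Symmetric dimethylarginine	dimethyl	R	28.0313
N6,N6-dimethyllysine	dimethyl	K	28.0313
N6,N6,N6-trimethyllysine	trimethyl	K	42.04695
Citrulline	citrulline	R	0.984016
Citrullination	citrulline	R	0.984016
Deamidated asparagine	deamidated	N	0.984016
Deamidation	deamidated		0.984016
Ubiquitination	gg	K	114.042927
GlyGly (K)	gg	K	114.042927
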