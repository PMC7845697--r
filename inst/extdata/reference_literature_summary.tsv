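set	cooccurrence_mean	cooccurrence_sd	jaccard_mean	fisher_significant_mean	fisher_significant_sd
high	0.87	0.18	1.07e-4	58.53	14.01
low	0.09	0.03	2.17e-8	13.46	7.42
random	0.23	0.11	4.31e-5	27.86	9.98
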