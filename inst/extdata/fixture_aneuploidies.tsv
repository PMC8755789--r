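subject_id	karyotype_label
D080	trisomy 21
D081	trisomy 21
D082	trisomy 21
D083	trisomy 21
D084	trisomy 21
D085	trisomy 21
D086	47,XXY
D087	47,XYY
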