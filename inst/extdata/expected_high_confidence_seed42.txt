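ctg001_orf04
ctg005_orf03
ctg007_orf02
ctg008_orf03
ctg011_orf06
ctg013_orf06
ctg014_orf04
ctg019_orf05
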