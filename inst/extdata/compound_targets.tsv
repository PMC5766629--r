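# compound -> experimentally validated key-target map of the four main alkaloids
matrine	CASP3
matrine	MMP2
matrine	MYC
oxymatrine	MMP2
oxymatrine	REG1A
sophoridine	MMP2
sophoridine	REG1A
N-methylcytisine	MMP2
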