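go:0030334	Regulation of cell migration	ACVRL1	APOE	BCL2	CDH13	CORO1A	IGF1R	KDR	MUC2	MUC5AC	ONECUT1	ONECUT2	PTPRK	RTN4	SST
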