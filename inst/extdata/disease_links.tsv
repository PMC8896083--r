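protein	disease	status
APOE	AD	stated
APOE	ALS	stated
APOE	FTD	stated
APOE	LBD	stated
APOE	PD	stated
APOE	BD/NCL	stated
CLU	AD	stated
CLU	PD	stated
CLU	MS	stated
TREM2	AD	stated
TREM2	ALS	stated
TREM2	FTD	stated
TREM2	PD	stated
BACE1	AD	stated
BACE1	PD	stated
PP2B	AD	stated
PP2B	ALS	stated
PP2B	HD	stated
PP2B	PD	stated
PP2B	MS	stated
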