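record	name	start	end
transcript	NM_005713.3	624	NA
domain	PH	23	117
domain	SRR	132	150
domain	FFAT	321	326
domain	START	389	618
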