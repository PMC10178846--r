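name	start	end
cluster1_SRR	132	141
cluster2_T166	166	166
cluster3_CCD	240	254
cluster4_FFAT	326	330
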