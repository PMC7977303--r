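INFLAMMATORY	synthetic example set	CCL5	CXCL9	CXCL10	GZMB	PRF1
TUBULAR	synthetic example set	UMOD	AQP2	SLC12A1	KCNJ1
ENDOTHELIAL	synthetic example set	PECAM1	VWF	CDH5
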