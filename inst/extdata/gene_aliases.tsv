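# alias	canonical
PLPP3	PPAP2B
LPAL2	LPA
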