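# Six-gene SMR worked example. All six pass the association threshold
# (p_primary < 5.24e-6); VAMP8 and MAT2A fail the HEIDI heterogeneity test
# (p_secondary < 0.05) and are discarded. The numeric p-values are
# illustrative placeholders consistent with that published pass/fail
# pattern; the original per-gene statistics are not reproduced here.
gene	p_primary	p_secondary
PSRC1	1.2e-9	0.31
LIPA	3.5e-8	0.12
SWAP70	8.9e-7	0.47
NT5C2	2.1e-6	0.08
VAMP8	4.0e-7	0.012
MAT2A	1.8e-6	0.034
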