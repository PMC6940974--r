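hsa:5728	PTEN, BZS, MMAC1; phosphatase and tensin homolog
hsa:324	APC, BTPS2, DP2; APC regulator of WNT signaling pathway
hsa:1793	DOCK1, DOCK180; dedicator of cytokinesis 1
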