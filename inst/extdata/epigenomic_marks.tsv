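mark	low_scoring	high_scoring	increase
H3K4me1	0.074	0.123	1.662
H3K4me3	0.010	0.046	4.600
H3K27ac	0.027	0.052	1.926
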