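method	recall	precision	f1	fp_per_correct	fp_per_mb
dynamic_negative_cnn	0.50	0.52	0.51	0.93	46.44
EP3	0.50	0.20	0.29	4.01	198.26
Basset	0.50	0.07	0.12	13.48	664.92
PromPredict	0.50	0.07	0.12	13.44	666.26
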