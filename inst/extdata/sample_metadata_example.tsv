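sample_id	day	productivity
BR_d20	20	0.4
BR_d31	31	0.7
BR_d45	45	1.2
BR_d56	56	2
BR_d64	64	2.8
BR_d74	74	3.9
BR_d84	84	3.2
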