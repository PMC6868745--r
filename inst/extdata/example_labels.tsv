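sample_id	label
T1	SCC
T2	ADC
T3	SCC
N1	NORMAL
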