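gene_id	T1	T2	T3	N1
KRT5	7.2	2.1	6.8	4.0
AGR2	3.1	6.5	2.2	4.5
NAPSA	2.0	8.1	1.9	5.0
TP63	6.6	1.4	7.0	4.1
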