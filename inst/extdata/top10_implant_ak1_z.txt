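1	ATGCCGTA
2	TATATAAT
3	TAATATAT
4	ATATATAA
5	ATTATATA
6	AATATATA
7	TTATATAT
8	ATATATTA
9	TATATATT
10	ATATTATA
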