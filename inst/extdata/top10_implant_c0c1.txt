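1	ATGCCGTA
2	TGCCGTAA
3	AATGCCGT
4	TATGCCGT
5	TGCCGTAT
6	GCCGTATA
7	TAATGCCG
8	ATATGCCG
9	GCCGTAAT
10	TGCCGTAG
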