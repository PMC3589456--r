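1	CGGGGGGC
2	CGGGAGAC
3	CGATGCCG
4	ACCCCCCC
5	CCCCCCCT
6	GCCGTAGC
7	GCACCCCC
8	CGGGTGGC
9	ATGCCGTA
10	GCACCCTC
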