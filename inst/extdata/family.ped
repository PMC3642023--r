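FAM1	1	0	0	2	1
FAM1	2	0	0	1	1
FAM1	3	2	1	1	1
FAM1	4	2	1	2	1
FAM1	5	2	1	1	1
FAM1	6	2	1	2	1
FAM1	7	2	1	1	1
FAM1	8	2	1	1	2
FAM1	9	2	1	2	1
FAM1	10	2	1	1	2
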