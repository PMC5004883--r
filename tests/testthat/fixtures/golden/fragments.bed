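chrT	0	1000	1	1	-
chrT	1000	2000	2	1	+
chrT	2000	3000	3	1	-
chrT	3000	4000	4	1	+
chrT	4000	5000	5	1	-
chrT	5000	6000	6	1	+
chrT	6000	7000	7	1	-
chrT	7000	8000	8	1	+
chrT	8000	9000	9	1	-
chrT	9000	10000	10	1	+
chrT	10000	11000	11	1	-
chrT	11000	12000	12	1	+
chrT	12000	13000	13	1	-
chrT	13000	14000	14	1	+
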