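chrom1	start1	end1	chrom2	start2	end2	raw_count
chrT	1000	2000	chrT	0	1000	6
chrT	1000	2000	chrT	2000	3000	6
chrT	1000	2000	chrT	4000	5000	10
chrT	1000	2000	chrT	6000	7000	9
chrT	1000	2000	chrT	8000	9000	5
chrT	1000	2000	chrT	10000	11000	9
chrT	1000	2000	chrT	12000	13000	8
chrT	3000	4000	chrT	0	1000	1
chrT	3000	4000	chrT	2000	3000	11
chrT	3000	4000	chrT	4000	5000	8
chrT	3000	4000	chrT	6000	7000	7
chrT	3000	4000	chrT	8000	9000	7
chrT	3000	4000	chrT	10000	11000	6
chrT	3000	4000	chrT	12000	13000	9
chrT	5000	6000	chrT	0	1000	8
chrT	5000	6000	chrT	2000	3000	5
chrT	5000	6000	chrT	4000	5000	8
chrT	5000	6000	chrT	6000	7000	7
chrT	5000	6000	chrT	8000	9000	8
chrT	5000	6000	chrT	10000	11000	5
chrT	5000	6000	chrT	12000	13000	7
chrT	7000	8000	chrT	0	1000	3
chrT	7000	8000	chrT	2000	3000	5
chrT	7000	8000	chrT	4000	5000	7
chrT	7000	8000	chrT	6000	7000	4
chrT	7000	8000	chrT	8000	9000	7
chrT	7000	8000	chrT	10000	11000	6
chrT	7000	8000	chrT	12000	13000	11
chrT	9000	10000	chrT	0	1000	4
chrT	9000	10000	chrT	2000	3000	7
chrT	9000	10000	chrT	4000	5000	5
chrT	9000	10000	chrT	6000	7000	8
chrT	9000	10000	chrT	8000	9000	7
chrT	9000	10000	chrT	10000	11000	4
chrT	9000	10000	chrT	12000	13000	9
chrT	11000	12000	chrT	0	1000	13
chrT	11000	12000	chrT	2000	3000	12
chrT	11000	12000	chrT	4000	5000	8
chrT	11000	12000	chrT	6000	7000	7
chrT	11000	12000	chrT	8000	9000	6
chrT	11000	12000	chrT	10000	11000	6
chrT	11000	12000	chrT	12000	13000	3
chrT	13000	14000	chrT	0	1000	4
chrT	13000	14000	chrT	2000	3000	11
chrT	13000	14000	chrT	4000	5000	6
chrT	13000	14000	chrT	6000	7000	3
chrT	13000	14000	chrT	8000	9000	10
chrT	13000	14000	chrT	10000	11000	6
chrT	13000	14000	chrT	12000	13000	8
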