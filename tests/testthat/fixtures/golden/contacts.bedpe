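chrom1	start1	end1	chrom2	start2	end2	raw_count	norm_freq
chrT	1000	2000	chrT	0	1000	6	17.647058823529413
chrT	1000	2000	chrT	2000	3000	6	17.647058823529413
chrT	1000	2000	chrT	4000	5000	10	29.411764705882351
chrT	1000	2000	chrT	6000	7000	9	26.470588235294116
chrT	1000	2000	chrT	8000	9000	5	14.705882352941176
chrT	1000	2000	chrT	10000	11000	9	26.470588235294116
chrT	1000	2000	chrT	12000	13000	8	23.52941176470588
chrT	3000	4000	chrT	0	1000	1	2.9411764705882351
chrT	3000	4000	chrT	2000	3000	11	32.352941176470594
chrT	3000	4000	chrT	4000	5000	8	23.52941176470588
chrT	3000	4000	chrT	6000	7000	7	20.588235294117649
chrT	3000	4000	chrT	8000	9000	7	20.588235294117649
chrT	3000	4000	chrT	10000	11000	6	17.647058823529413
chrT	3000	4000	chrT	12000	13000	9	26.470588235294116
chrT	5000	6000	chrT	0	1000	8	23.52941176470588
chrT	5000	6000	chrT	2000	3000	5	14.705882352941176
chrT	5000	6000	chrT	4000	5000	8	23.52941176470588
chrT	5000	6000	chrT	6000	7000	7	20.588235294117649
chrT	5000	6000	chrT	8000	9000	8	23.52941176470588
chrT	5000	6000	chrT	10000	11000	5	14.705882352941176
chrT	5000	6000	chrT	12000	13000	7	20.588235294117649
chrT	7000	8000	chrT	0	1000	3	8.8235294117647065
chrT	7000	8000	chrT	2000	3000	5	14.705882352941176
chrT	7000	8000	chrT	4000	5000	7	20.588235294117649
chrT	7000	8000	chrT	6000	7000	4	11.76470588235294
chrT	7000	8000	chrT	8000	9000	7	20.588235294117649
chrT	7000	8000	chrT	10000	11000	6	17.647058823529413
chrT	7000	8000	chrT	12000	13000	11	32.352941176470594
chrT	9000	10000	chrT	0	1000	4	11.76470588235294
chrT	9000	10000	chrT	2000	3000	7	20.588235294117649
chrT	9000	10000	chrT	4000	5000	5	14.705882352941176
chrT	9000	10000	chrT	6000	7000	8	23.52941176470588
chrT	9000	10000	chrT	8000	9000	7	20.588235294117649
chrT	9000	10000	chrT	10000	11000	4	11.76470588235294
chrT	9000	10000	chrT	12000	13000	9	26.470588235294116
chrT	11000	12000	chrT	0	1000	13	38.235294117647065
chrT	11000	12000	chrT	2000	3000	12	35.294117647058826
chrT	11000	12000	chrT	4000	5000	8	23.52941176470588
chrT	11000	12000	chrT	6000	7000	7	20.588235294117649
chrT	11000	12000	chrT	8000	9000	6	17.647058823529413
chrT	11000	12000	chrT	10000	11000	6	17.647058823529413
chrT	11000	12000	chrT	12000	13000	3	8.8235294117647065
chrT	13000	14000	chrT	0	1000	4	11.76470588235294
chrT	13000	14000	chrT	2000	3000	11	32.352941176470594
chrT	13000	14000	chrT	4000	5000	6	17.647058823529413
chrT	13000	14000	chrT	6000	7000	3	8.8235294117647065
chrT	13000	14000	chrT	8000	9000	10	29.411764705882351
chrT	13000	14000	chrT	10000	11000	6	17.647058823529413
chrT	13000	14000	chrT	12000	13000	8	23.52941176470588
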