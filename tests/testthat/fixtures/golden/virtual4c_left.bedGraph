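chrT	2000	4000	10.294117647058824
chrT	4000	6000	26.470588235294116
chrT	6000	8000	17.647058823529413
chrT	8000	10000	13.235294117647058
chrT	10000	12000	32.352941176470594
chrT	12000	14000	17.647058823529409
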