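label	chrT:0-2000	chrT:2000-4000	chrT:4000-6000	chrT:6000-8000	chrT:8000-10000	chrT:10000-12000	chrT:12000-14000
chrT:0-2000	17.647058823529413	10.294117647058824	26.470588235294116	17.647058823529413	13.235294117647058	32.352941176470594	17.647058823529409
chrT:2000-4000	10.294117647058824	32.352941176470594	19.117647058823529	17.647058823529413	20.588235294117649	26.47058823529412	29.411764705882355
chrT:4000-6000	26.470588235294116	19.117647058823529	23.52941176470588	20.588235294117649	19.117647058823529	19.117647058823529	19.117647058823529
chrT:6000-8000	17.647058823529413	17.647058823529413	20.588235294117649	11.76470588235294	22.058823529411764	19.117647058823529	20.588235294117652
chrT:8000-10000	13.235294117647058	20.588235294117649	19.117647058823529	22.058823529411764	20.588235294117649	14.705882352941178	27.941176470588232
chrT:10000-12000	32.352941176470594	26.47058823529412	19.117647058823529	19.117647058823529	14.705882352941178	17.647058823529413	13.23529411764706
chrT:12000-14000	17.647058823529409	29.411764705882355	19.117647058823529	20.588235294117652	27.941176470588232	13.23529411764706	23.52941176470588
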