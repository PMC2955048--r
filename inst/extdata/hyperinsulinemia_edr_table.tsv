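id	gene	raw_p	x_i	f_i	N_prime	EDR
M72885_rna1_s_at	GOS2	0.00018432	309.453094	5.318301	2	0.00000028
X15729_s_at	DDX5	0.00044674	2.773653	1.332583	4	0.00193717
M34516_r_at	IGL@	0.00321646	10.316779	1.807361	27	0.01042631
D11428_at	PMP22	0.00342428	20.312435	1.910159	30	0.00555663
HG3514-HT3708_at	Tropomyosin	0.00437053	41.545886	1.188196	33	0.01844629
L20971_at	PDE4B	0.00494670	3.348770	1.998387	42	0.06214142
U33448_s_at	LTB4R	0.00625588	0.582200	1.066264	53	1
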