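name	guide_class	protospacer	pam	specificity	chari	doench	moreno_mateos	observed_efficiency	efficiency_median	chimerism
VQ33-42	G-N18	GATGAGGAGATATTATCTG	AGG	95	79	72	57	75.0	92.2	5.4
VQ33-38	G-N19	GCCTTAACGTATTGATCATT	AGG	96	2	36	28	84.4	94.6	5.9
VQ33-1	G-N19	GGGTCATCGTTGCTTCTCAG	TGG	100	58	66	56	75.4	94.2	4.5
VQ19-6	G-N19	GGGACTGTTAAGTGCAAGCT	TGG	99	28	48	45	34.4	19.6	3.5
VQ19-34	G-N19	GCGGAGAGTCTGGAGATCTT	GGG	99	60	44	50	66.1	82.3	7.6
GRXS17-4	G-N19	GACCTTCGAGCCGAGCTCGG	AGG	100	99	64	58	67.3	83.2	4.2
GLB3-3	G-N19	GATAAGGCATCGGTGTTAAG	CGG	100	88	62	56	77.7	96.1	6.6
JAM2-109	G-N19	GGAGATTTGGTTCTCTGTTG	GGG	97	31	48	53	88.6	97.7	3.4
JAM2-140	G-N20	TATTGCAGAGAGCCTAAAGA	AGG	96	80	56	36	26.4	4.5	2.5
GRXS17-133	G-N20	CTTGATAACTTGCGCCAGAG	CGG	84	86	62	57	NA	NA	NA
GRXS17-67	G-N20	ATTATGGAGCTAAGTGAGAG	TGG	98	87	63	28	NA	NA	NA
WRKY20-201	G-N20	ACTTCCCAAAATGACTCCAG	AGG	100	97	69	64	NA	NA	NA
WRKY20-39	G-N19	GTATGGCTGCACAAGAAGAA	AGG	96	90	54	42	NA	NA	NA
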