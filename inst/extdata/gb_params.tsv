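atom	charge	radius	scale
N	-0.4157	1.55	0.79
H	0.2719	1.30	0.85
CA	0.1144	1.70	0.72
C	0.5973	1.70	0.72
O	-0.5679	1.50	0.85
CB	0.0000	1.70	0.72
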