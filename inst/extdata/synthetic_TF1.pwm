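0.88	0.02	0.04	0.02	0.90	0.03	0.02	0.05
0.04	0.90	0.02	0.02	0.04	0.02	0.91	0.03
0.04	0.04	0.92	0.03	0.03	0.03	0.04	0.02
0.04	0.04	0.02	0.93	0.03	0.92	0.03	0.90
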