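dataset,patient,tumor_pct,healthy_pct
phantom,1,0.16,1.89
phantom,2,1.03,1.82
phantom,3,0.12,2.32
phantom,4,0,2.22
hgg,1,5.13,0.93
hgg,2,0.18,0.95
hgg,3,0,3.08
hgg,4,0,3.13
hgg,5,1.27,0.82
hgg,6,0,3.49
lgg,1,2.24,1.84
lgg,2,1.78,2.15
lgg,3,0.77,2.28
lgg,4,0,2.8
lgg,5,0,5.67
lgg,6,0,4.4
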