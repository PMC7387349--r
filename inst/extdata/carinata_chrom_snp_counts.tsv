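chromosome	n_snps
B1	771
B2	1261
B3	1207
B4	599
B5	894
B6	809
B7	920
B8	991
C1	213
C2	266
C3	503
C4	300
C5	262
C6	270
C7	302
C8	348
C9	283
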