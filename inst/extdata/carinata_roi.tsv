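region_id	chrom	start	end
B1	B1	36151527	37051510
B3	B3	6240446	11108537
B8	B8	19335162	23732292
C2-1	C2	13922159	16610327
C2-2	C2	27814654	29475511
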