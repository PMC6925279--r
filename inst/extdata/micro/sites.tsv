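#site_id	chrom	start	end	family	superfamily	type
s1	chr1	1096	1100	Copia_fam1	Copia	A
s2	chr1	5296	5300	Gypsy_fam1	Gypsy	A
s3	chr1	9496	9500	LINE_fam1	LINE	B
s4	chr1	14096	14100	Mariner_fam1	Mariner	B
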