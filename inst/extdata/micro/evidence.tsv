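#site_id	id	split_up	split_down	discordant
s1	d1	2	1	0
s2	d2	3	0	0
s2	t1	1	1	1
s3	d3	1	1	0
s3	t2	2	2	2
s4	t3	5	5	0
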