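#site_id	d1	d2	d3	t1	t2	t3
s1	30	4	5	100	101	50
s2	5	50	100	20	6	4
s3	101	50	4	50	30	50
s4	50	50	50	101	4	30
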