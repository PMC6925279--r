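#site_id	d1	d2	d3	t1	t2	t3
s1	C	NA	N	N	NA	N
s2	N	N	N	C	N	NA
s3	NA	N	NA	N	C	N
s4	N	N	N	NA	NA	C
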