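#id	population	clade	ploidy	coverage
d1	dA_p1	dA	2	9.5
d2	dA_p1	dA	2	8.0
d3	dA_p2	dA	2	7.2
t1	tA_p1	tA	4	10.1
t2	tA_p1	tA	4	8.8
t3	tA_p2	tA	4	9.0
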