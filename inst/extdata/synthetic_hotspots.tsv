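gene	protein_change	q_value
EP300	p.D1399N	6.9e-22
EP300	p.Y1467C	4.8e-07
EP300	p.M1470T	0.019
TP53	p.R248W	1e-30
HRAS	p.G12D	1e-25
PIK3CA	p.E545K	1e-20
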