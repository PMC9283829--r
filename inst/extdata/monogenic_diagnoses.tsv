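family	ff_pct	gene	variant	combined	bayes	haplo	correct
SFY-10	16	PTS	c.73C>G	C/C	C/C	NA	TRUE
SFY-10	16	PTS	c.155A>G	A/G	A/G	A/G	TRUE
SFY-15	16	DMD	c.187-2A>T	A/T	A/T	NA	TRUE
SFY-32	8	CDH23	c.8371delC	AC/A	NA	AC/A	TRUE
SFY-32	8	CDH23	c.1606C>T	C/T	C/T	NA	TRUE
SFY-05	20	B3GALNT2	c.181C>T	C/C	C/C	not in block	FALSE
SFY-05	20	B3GALNT2	c.261-2A>G	A/G	A/G	NA	TRUE
SFY-18	14	GPR143	c.885+748G>A	G/A	G/A	G/A	TRUE
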