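role	resname	atom	hydrogens
donor	*	N	H HN HT1 HT2 HT3 H1 H2 H3
acceptor	*	O
acceptor	*	OXT
acceptor	*	OT1
acceptor	*	OT2
donor	ARG	NE	HE
donor	ARG	NH1	HH11 HH12
donor	ARG	NH2	HH21 HH22
acceptor	ASN	OD1
donor	ASN	ND2	HD21 HD22
acceptor	ASP	OD1
acceptor	ASP	OD2
donor	CYS	SG	HG HG1
acceptor	GLN	OE1
donor	GLN	NE2	HE21 HE22
acceptor	GLU	OE1
acceptor	GLU	OE2
donor	HIS	ND1	HD1
donor	HIS	NE2	HE2
acceptor	HIS	ND1
acceptor	HIS	NE2
donor	HSD	ND1	HD1
acceptor	HSD	NE2
donor	HSE	NE2	HE2
acceptor	HSD	ND1
donor	LYS	NZ	HZ1 HZ2 HZ3
acceptor	MET	SD
donor	SER	OG	HG HG1
acceptor	SER	OG
donor	THR	OG1	HG1
acceptor	THR	OG1
donor	TRP	NE1	HE1
donor	TYR	OH	HH
acceptor	TYR	OH
donor	HOH	OH2	H1 H2
donor	HOH	O	H1 H2
acceptor	HOH	OH2
acceptor	HOH	O
donor	TIP3	OH2	H1 H2
acceptor	TIP3	OH2
donor	FAD	N3	H3 HN3
acceptor	FAD	O2
acceptor	FAD	O4
acceptor	FAD	N1
acceptor	FAD	N5
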