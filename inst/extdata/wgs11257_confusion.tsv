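cluster	ADMIX	AFR	AMR	CSA	EAS	EUR	MDE
EAS	22	0	0	0	236	0	0
AFR	385	1234	0	0	0	0	0
CSA	104	0	0	280	0	0	0
MDE	777	0	0	0	0	77	265
AMR	435	0	132	0	0	0	0
EUR	662	0	0	0	0	6648	0
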