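id	kind	substrates	products	modifier	params	compartment	note
1	michaelis_menten	Elk1	pElk1	ERK	r01_kcat;r01_Km	nucleus	Elk-1 phosphorylation by ERK
2	michaelis_menten	pElk1	Elk1		r02_Vmax;r02_Km	nucleus	pElk-1 dephosphorylation
3	first_order	pElk1		 	r03_k	nucleus	pElk-1 degradation
4	michaelis_menten	cFos_n	pcFos	FRK	r04_kcat;r04_Km	nucleus	c-Fos phosphorylation by FRK
5	michaelis_menten	pcFos	cFos_n		r05_Vmax;r05_Km	nucleus	pc-Fos dephosphorylation
6	first_order	cFos_n		 	r06_k	nucleus	c-Fos degradation
7	first_order	pcFos		 	r07_k	nucleus	pc-Fos degradation
8	michaelis_menten	pcFos	ppcFos	FRK	r08_kcat;r08_Km	nucleus	pc-Fos phosphorylation by FRK
9	michaelis_menten	ppcFos	pcFos		r09_Vmax;r09_Km	nucleus	ppc-Fos dephosphorylation
10	michaelis_menten	cJun_n	pcJun	JNK	r10_kcat;r10_Km	nucleus	c-Jun phosphorylation by JNK
11	michaelis_menten	pcJun	cJun_n		r11_Vmax;r11_Km	nucleus	pc-Jun dephosphorylation
12	first_order	ppcFos		 	r12_k	nucleus	ppc-Fos degradation
13	michaelis_menten	pcJun	ppcJun	JNK	r13_kcat;r13_Km	nucleus	pc-Jun phosphorylation by JNK
14	michaelis_menten	ppcJun	pcJun		r14_Vmax;r14_Km	nucleus	ppc-Jun dephosphorylation
15	first_order	cJun_n		 	r15_k	nucleus	c-Jun degradation
16	first_order	pcJun		 	r16_k	nucleus	pc-Jun degradation
17	michaelis_menten	ATF2	pATF2	JNK	r17_kcat;r17_Km	nucleus	ATF-2 phosphorylation by JNK
18	michaelis_menten	pATF2	ATF2		r18_Vmax;r18_Km	nucleus	pATF-2 dephosphorylation
19	michaelis_menten	pATF2	ppATF2	JNK	r19_kcat;r19_Km	nucleus	pATF-2 phosphorylation by JNK
20	michaelis_menten	ppATF2	pATF2		r20_Vmax;r20_Km	nucleus	ppATF-2 dephosphorylation
21	mass_action	ppcFos;ppcJun	FosJun		r21_kon;r21_koff	nucleus	ppc-Fos:ppc-Jun heterodimerization
22	first_order	ppcJun		 	r22_k	nucleus	ppc-Jun degradation
23	michaelis_menten	FosJun	cFos_n;cJun_n		r23_Vmax;r23_Km	nucleus	ppc-Fos:ppc-Jun dissociation and dephosphorylation
24	mass_action	2*ppcJun	JunJun		r24_kon;r24_koff	nucleus	ppc-Jun:ppc-Jun homodimerization
25	first_order	ppATF2		 	r25_k	nucleus	ppATF-2 degradation
26	michaelis_menten	JunJun	2*cJun_n		r26_Vmax;r26_Km	nucleus	ppc-Jun:ppc-Jun dissociation and dephosphorylation
27	mass_action	ppcJun;ppATF2	JunATF		r27_kon;r27_koff	nucleus	ppc-Jun:ppATF-2 dimerization
28	michaelis_menten	JunATF	cJun_n;ATF2		r28_Vmax;r28_Km	nucleus	ppc-Jun:ppATF-2 dissociation and dephosphorylation
29	mass_action	pElk1;FosProm	FosProm_pElk1		r29_kon;r29_koff	nucleus	pElk-1 binding to c-Fos promoter
30	first_order	FosProm_pElk1	FosProm_pElk1;cFos_pre	 	r30_k	nucleus	c-Fos transcription from bound promoter
31	first_order	FosProm	FosProm;cFos_pre	 	r31_k	nucleus	basal c-Fos transcription
32	first_order	cFos_pre	cFos_mRNA	 	r32_k	nucleus	c-Fos pre-mRNA processing and export
33	first_order	cFos_mRNA		 	r33_k	cytosol	c-Fos mRNA degradation
34	first_order	cFos_mRNA	cFos_mRNA;cFos_cyt	 	r34_k	cytosol	c-Fos translation
35	first_order	cFos_cyt	cFos_n	 	r35_k	cytosol	c-Fos nuclear import
36	mass_action	JunATF;JunProm	JunProm_JunATF		r36_kon;r36_koff	nucleus	ppc-Jun:ppATF-2 binding to c-Jun promoter
37	first_order	JunProm_JunATF	JunProm_JunATF;cJun_pre	 	r37_k	nucleus	c-Jun transcription from bound promoter
38	first_order	JunProm	JunProm;cJun_pre	 	r38_k	nucleus	basal c-Jun transcription
39	first_order	cJun_pre	cJun_mRNA	 	r39_k	nucleus	c-Jun pre-mRNA processing and export
40	first_order	cJun_mRNA		 	r40_k	cytosol	c-Jun mRNA degradation
41	first_order	cJun_mRNA	cJun_mRNA;cJun_cyt	 	r41_k	cytosol	c-Jun translation
42	first_order	cJun_cyt	cJun_n	 	r42_k	cytosol	c-Jun nuclear import
43	mass_action	FosJun;THProm	THProm_FosJun		r43_kon;r43_koff	nucleus	ppc-Fos:ppc-Jun binding to TH promoter
44	first_order	THProm_FosJun	THProm_FosJun;TH_pre	 	r44_k	nucleus	TH transcription from heterodimer-bound promoter
45	mass_action	JunJun;THProm	THProm_JunJun		r45_kon;r45_koff	nucleus	ppc-Jun:ppc-Jun binding to TH promoter
46	first_order	THProm_JunJun	THProm_JunJun;TH_pre	 	r46_k	nucleus	TH transcription from homodimer-bound promoter
47	first_order	TH_pre	TH_mRNA	 	r47_k	nucleus	TH pre-mRNA processing and export
48	first_order	TH_mRNA		 	r48_k	cytosol	TH mRNA degradation
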