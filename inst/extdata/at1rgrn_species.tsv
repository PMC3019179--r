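name	compartment	role	init
ERK	nucleus	input	0
FRK	nucleus	input	0
JNK	nucleus	input	0
Elk1	nucleus	state	ic_Elk1
pElk1	nucleus	state	0
ATF2	nucleus	state	ic_ATF2
pATF2	nucleus	state	0
ppATF2	nucleus	state	0
cFos_n	nucleus	state	0
pcFos	nucleus	state	0
ppcFos	nucleus	state	0
cJun_n	nucleus	state	0
pcJun	nucleus	state	0
ppcJun	nucleus	state	0
FosJun	nucleus	state	0
JunJun	nucleus	state	0
JunATF	nucleus	state	0
FosProm	nucleus	state	promoter
FosProm_pElk1	nucleus	state	0
JunProm	nucleus	state	promoter
JunProm_JunATF	nucleus	state	0
THProm	nucleus	state	promoter
THProm_FosJun	nucleus	state	0
THProm_JunJun	nucleus	state	0
cFos_pre	nucleus	state	0
cJun_pre	nucleus	state	0
TH_pre	nucleus	state	0
cFos_mRNA	cytosol	state	0
cJun_mRNA	cytosol	state	0
TH_mRNA	cytosol	state	0
cFos_cyt	cytosol	state	0
cJun_cyt	cytosol	state	0
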