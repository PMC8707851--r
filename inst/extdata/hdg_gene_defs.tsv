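gene	cluster	group	length_bp
almA	almA	aliphatic	1500
alkB	alkB	aliphatic	1200
cyp153	cyp153	aliphatic	1350
ladA	ladA	aliphatic	1300
pmoA	pmoABC	aliphatic	750
pmoB	pmoABC	aliphatic	1250
pmoC	pmoABC	aliphatic	780
bmoB	bmoBCDXYZ	aliphatic	1060
bmoC	bmoBCDXYZ	aliphatic	1030
bmoD	bmoBCDXYZ	aliphatic	520
bmoX	bmoBCDXYZ	aliphatic	1590
bmoY	bmoBCDXYZ	aliphatic	1170
bmoZ	bmoBCDXYZ	aliphatic	1010
adh1	adh1	various	1050
adh2	adh2	various	1040
adhP	adhP	various	1010
frmA	frmA	various	1110
ligA	ligAB	various	860
ligB	ligAB	various	910
dmpK	dmpKLMNOP	MAH	280
dmpL	dmpKLMNOP	MAH	990
dmpM	dmpKLMNOP	MAH	270
dmpN	dmpKLMNOP	MAH	1550
dmpO	dmpKLMNOP	MAH	360
dmpP	dmpKLMNOP	MAH	1060
tmoA	tmoABCDEF	MAH	1490
tmoB	tmoABCDEF	MAH	260
tmoC	tmoABCDEF	MAH	340
tmoD	tmoABCDEF	MAH	310
tmoE	tmoABCDEF	MAH	990
tmoF	tmoABCDEF	MAH	980
bsdC	bsdCD	MAH	1420
bsdD	bsdCD	MAH	620
pchC	pchCF	MAH	1580
pchF	pchCF	MAH	1600
xylE	xylE	MAH	920
catA	catA	MAH	930
nahC	nahC	PAH	910
nidA	nidAB	PAH	1360
nidB	nidAB	PAH	520
dbfA1	dbfA1A2	PAH	1370
dbfA2	dbfA1A2	PAH	500
phnAc	phnAc	PAH	1340
ndoB	ndoB	PAH	1380
pcaG	pcaGH	PAH	620
pcaH	pcaGH	PAH	730
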