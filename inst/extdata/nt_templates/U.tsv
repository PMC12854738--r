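atom	element	x	y	z
OP3	O	-2.122	1.033	-4.690
P	P	-1.030	0.047	-4.037
OP1	O	-1.679	-1.228	-3.660
OP2	O	0.138	-0.241	-5.107
O5'	O	-0.399	0.736	-2.726
C5'	C	0.557	-0.182	-2.196
C4'	C	1.197	0.415	-0.942
O4'	O	0.194	0.645	0.074
C3'	C	2.181	-0.588	-0.301
O3'	O	3.524	-0.288	-0.686
C2'	C	1.995	-0.383	1.218
O2'	O	3.219	0.046	1.819
C1'	C	0.922	0.723	1.319
N1	N	0.028	0.464	2.451
C2	C	-0.690	-0.671	2.486
O2	O	-0.587	-1.474	1.580
N3	N	-1.515	-0.936	3.517
C4	C	-1.641	-0.055	4.530
O4	O	-2.391	-0.292	5.460
C5	C	-0.894	1.146	4.502
C6	C	-0.070	1.384	3.459
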