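atom	element	x	y	z
OP3	O	2.147	-1.021	-4.678
P	P	1.049	-0.039	-4.028
OP1	O	1.692	1.237	-3.646
OP2	O	-0.116	0.246	-5.102
O5'	O	0.415	-0.733	-2.721
C5'	C	-0.546	0.181	-2.193
C4'	C	-1.189	-0.419	-0.942
O4'	O	-0.190	-0.648	0.076
C3'	C	-2.178	0.583	-0.307
O3'	O	-3.518	0.283	-0.703
C2'	C	-2.001	0.373	1.215
O2'	O	-3.228	-0.059	1.806
C1'	C	-0.924	-0.729	1.317
N1	N	-0.036	-0.470	2.453
C2	C	0.652	0.683	2.514
O2	O	0.529	1.504	1.620
N3	N	1.467	0.945	3.535
C4	C	1.620	0.070	4.520
N4	N	2.464	0.350	5.569
C5	C	0.916	-1.151	4.483
C6	C	0.087	-1.399	3.442
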