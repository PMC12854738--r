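atom	element	x	y	z
OP3	O	2.135	-1.141	-5.313
P	P	1.024	-0.137	-4.723
OP1	O	1.633	1.190	-4.488
OP2	O	-0.183	0.005	-5.778
O5'	O	0.456	-0.720	-3.334
C5'	C	-0.520	0.209	-2.863
C4'	C	-1.101	-0.287	-1.538
O4'	O	-0.064	-0.383	-0.538
C3'	C	-2.105	0.739	-0.969
O3'	O	-3.445	0.360	-1.287
C2'	C	-1.874	0.684	0.558
O2'	O	-3.065	0.271	1.231
C1'	C	-0.755	-0.367	0.729
N9	N	0.158	0.029	1.803
C8	C	1.265	0.813	1.672
N7	N	1.843	0.963	2.828
C5	C	1.143	0.292	3.773
C6	C	1.290	0.091	5.156
N6	N	2.344	0.664	5.846
N1	N	0.391	-0.656	5.787
C2	C	-0.617	-1.206	5.136
N3	N	-0.792	-1.051	3.841
C4	C	0.056	-0.320	3.126
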