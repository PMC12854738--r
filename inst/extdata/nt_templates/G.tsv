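atom	element	x	y	z
OP3	O	-1.945	-1.360	5.599
P	P	-0.911	-0.277	5.008
OP1	O	-1.598	1.022	4.844
OP2	O	0.325	-0.105	6.025
O5'	O	-0.365	-0.780	3.580
C5'	C	0.542	0.217	3.109
C4'	C	1.100	-0.200	1.748
O4'	O	0.033	-0.318	0.782
C3'	C	2.025	0.898	1.182
O3'	O	3.395	0.582	1.439
C2'	C	1.741	0.884	-0.338
O2'	O	2.927	0.560	-1.066
C1'	C	0.675	-0.220	-0.507
N9	N	-0.297	0.162	-1.534
C8	C	-1.440	0.880	-1.334
N7	N	-2.066	1.037	-2.464
C5	C	-1.364	0.431	-3.453
C6	C	-1.556	0.279	-4.846
O6	O	-2.534	0.755	-5.397
N1	N	-0.626	-0.401	-5.551
C2	C	0.459	-0.934	-4.923
N2	N	1.384	-1.626	-5.664
N3	N	0.649	-0.800	-3.630
C4	C	-0.226	-0.134	-2.868
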