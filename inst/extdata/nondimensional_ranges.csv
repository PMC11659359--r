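set_id,name,lo,hi,varied,shifted
1,A1,,,FALSE,FALSE
1,K0,0.5814,0.7106,TRUE,FALSE
1,B1,0.2808,0.3432,TRUE,FALSE
1,A2,0.2073,0.2503,TRUE,TRUE
1,K1,0.1800,0.2230,TRUE,TRUE
1,K2,0.0972,0.1188,TRUE,FALSE
1,B2,0.0387,0.0473,TRUE,FALSE
2,A1,1.3995,1.7105,TRUE,FALSE
2,K0,,,FALSE,FALSE
2,B1,0.4365,0.5335,TRUE,FALSE
2,A2,0.3230,0.3900,TRUE,TRUE
2,K1,0.2805,0.3475,TRUE,TRUE
2,K2,0.1503,0.1837,TRUE,FALSE
2,B2,0.0603,0.0737,TRUE,FALSE
3,A1,2.8863,3.5277,TRUE,FALSE
3,K0,1.8567,2.2693,TRUE,FALSE
3,B1,,,FALSE,FALSE
3,A2,0.6651,0.8031,TRUE,TRUE
3,K1,0.5778,0.7158,TRUE,TRUE
3,K2,0.3105,0.3795,TRUE,FALSE
3,B2,0.1242,0.1518,TRUE,FALSE
4,A1,4.1805,5.1095,TRUE,FALSE
4,K0,2.6892,3.2868,TRUE,FALSE
4,B1,1.3032,1.5928,TRUE,FALSE
4,A2,,,FALSE,FALSE
4,K1,0.8364,1.0364,TRUE,TRUE
4,K2,0.4500,0.5500,TRUE,FALSE
4,B2,0.1791,0.2189,TRUE,FALSE
5,A1,4.1805,5.1095,TRUE,FALSE
5,K0,2.6892,3.2868,TRUE,FALSE
5,B1,1.3032,1.5928,TRUE,FALSE
5,A2,0.9649,1.1649,TRUE,TRUE
5,K1,,,FALSE,FALSE
5,K2,0.4500,0.5500,TRUE,FALSE
5,B2,0.1791,0.2189,TRUE,FALSE
6,A1,8.3610,10.2190,TRUE,FALSE
6,K0,5.3784,6.5736,TRUE,FALSE
6,B1,2.6073,3.1867,TRUE,FALSE
6,A2,1.9277,2.3277,TRUE,TRUE
6,K1,1.6750,2.0750,TRUE,TRUE
6,K2,,,FALSE,FALSE
6,B2,0.3582,0.4378,TRUE,FALSE
7,A1,20.9871,25.6509,TRUE,FALSE
7,K0,13.5000,16.5000,TRUE,FALSE
7,B1,6.5439,7.9981,TRUE,FALSE
7,A2,4.8384,5.8424,TRUE,TRUE
7,K1,4.2043,5.2083,TRUE,TRUE
7,K2,2.2590,2.7610,TRUE,FALSE
7,B2,,,FALSE,FALSE
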