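pair,role,restype,atom,x,y,z
GC,X,G,N1,-0.5743,0.2434,0
GC,X,G,C2,-1.1819,1.4935,0
GC,X,G,N3,-2.5684,1.5924,0
GC,X,G,C4,-3.3472,0.4411,0
GC,X,G,C5,-2.7396,-0.809,0
GC,X,G,C6,-1.3531,-0.9079,0
GC,X,G,N9,-4.724,0.2496,0
GC,X,G,C8,-4.9672,-1.119,0
GC,X,G,N7,-3.7408,-1.7732,0
GC,X,G,O6,-0.8155,-2.0142,0
GC,X,G,N2,-0.431,2.6034,0
GC,X,G,H1,0.4332,0.1715,0
GC,X,G,H21,-0.8725,3.5118,0
GC,X,G,H22,0.5764,2.5316,0
GC,X,G,C1',-6.1955,0.4078,0
GC,X,G,C2',-6.9589,1.4454,-0.55
GC,X,G,O2',-6.5659,2.761,-0.75
GC,X,G,HO2',-7.1054,3.5431,-0.95
GC,X,G,C3',-8.1894,1.2258,-0.3
GC,X,G,O3',-8.9827,2.2666,0.25
GC,X,G,O4',-7.0734,-0.5538,0.4
GC,X,G,C4',-8.3835,-0.1111,0.45
GC,X,G,C5',-9.1368,-1.0359,1.3
GC,X,G,O5',-9.9078,-0.0226,-0.15
GC,X,G,P,-10.6361,1.3884,-2
GC,X,G,OP1,-10.4891,0.4171,-0.9
GC,X,G,OP2,-11.9981,0.8811,-2.55
GC,Y,C,N1,4.4281,1.1301,0
GC,Y,C,C2,3.0424,1.2405,0
GC,Y,C,N3,2.254,0.0957,0
GC,Y,C,C4,2.8512,-1.1595,0
GC,Y,C,C5,4.2368,-1.2699,0
GC,Y,C,C6,5.0253,-0.1251,0
GC,Y,C,O2,2.514,2.3512,0
GC,Y,C,N4,2.0912,-2.2631,0
GC,Y,C,H41,2.5251,-3.1751,0
GC,Y,C,H42,1.0844,-2.1828,0
GC,Y,C,C1',5.4711,2.1801,0
GC,Y,C,C2',5.4103,3.4668,0.55
GC,Y,C,O2',4.2764,4.2409,0.75
GC,Y,C,HO2',4.2026,5.1882,0.95
GC,Y,C,C3',6.5043,4.0714,0.3
GC,Y,C,O3',6.4647,5.3795,-0.25
GC,Y,C,O4',6.7587,1.9863,-0.4
GC,Y,C,C4',7.4973,3.1555,-0.45
GC,Y,C,C5',8.6648,2.9118,-1.3
GC,Y,C,O5',8.6253,4.1845,0.15
GC,Y,C,P,8.302,5.7391,2
GC,Y,C,OP1,8.7997,4.8922,0.9
GC,Y,C,OP2,9.6793,6.2032,2.55
AU,X,A,N1,-0.6152,0.4808,0
AU,X,A,C2,-1.2025,1.7407,0
AU,X,A,N3,-2.5872,1.8619,0
AU,X,A,C4,-3.3846,0.7234,0
AU,X,A,C5,-2.7973,-0.5364,0
AU,X,A,C6,-1.4126,-0.6577,0
AU,X,A,N9,-4.7643,0.5541,0
AU,X,A,C8,-5.0296,-0.8103,0
AU,X,A,N7,-3.814,-1.4843,0
AU,X,A,N6,-0.8464,-1.8722,0
AU,X,A,H61,0.1597,-1.9604,0
AU,X,A,H62,-1.4258,-2.6995,0
AU,X,A,C1',-6.1961,0.9286,0
AU,X,A,C2',-6.7975,2.0678,-0.55
AU,X,A,O2',-6.214,3.3106,-0.75
AU,X,A,HO2',-6.6317,4.1641,-0.95
AU,X,A,C3',-8.047,2.0328,-0.3
AU,X,A,O3',-8.6773,3.1796,0.25
AU,X,A,O4',-7.2067,0.1076,0.4
AU,X,A,C4',-8.4369,0.7394,0.45
AU,X,A,C5',-9.3188,-0.0636,1.3
AU,X,A,O5',-9.9313,1.0527,-0.15
AU,X,A,P,-10.4425,2.556,-2
AU,X,A,OP1,-10.441,1.5736,-0.9
AU,X,A,OP2,-11.8647,2.256,-2.55
AU,Y,U,N1,4.4694,1.0691,0
AU,Y,U,C2,3.0899,1.2398,0
AU,Y,U,N3,2.2523,0.1305,0
AU,Y,U,C4,2.7941,-1.1495,0
AU,Y,U,C5,4.1736,-1.3203,0
AU,Y,U,C6,5.0112,-0.211,0
AU,Y,U,O2,2.6104,2.3725,0
AU,Y,U,O4,2.0529,-2.1311,0
AU,Y,U,H3,1.2499,0.2546,0
AU,Y,U,C1',5.5588,2.0708,0
AU,Y,U,C2',5.5562,3.359,0.55
AU,Y,U,O2',4.4584,4.1835,0.75
AU,Y,U,HO2',4.4275,5.1332,0.95
AU,Y,U,C3',6.6764,3.9136,0.3
AU,Y,U,O3',6.6959,5.2221,-0.25
AU,Y,U,O4',6.8363,1.8191,-0.4
AU,Y,U,C4',7.627,2.9537,-0.45
AU,Y,U,C5',8.7823,2.6575,-1.3
AU,Y,U,O5',8.8003,3.9307,0.15
AU,Y,U,P,8.5476,5.4983,2
AU,Y,U,OP1,9.0066,4.6298,0.9
AU,Y,U,OP2,9.9445,5.8997,2.55
CG,X,C,N1,-4.4281,1.1301,0
CG,X,C,C2,-3.0424,1.2405,0
CG,X,C,N3,-2.254,0.0957,0
CG,X,C,C4,-2.8512,-1.1595,0
CG,X,C,C5,-4.2368,-1.2699,0
CG,X,C,C6,-5.0253,-0.1251,0
CG,X,C,O2,-2.514,2.3512,0
CG,X,C,N4,-2.0912,-2.2631,0
CG,X,C,H41,-2.5251,-3.1751,0
CG,X,C,H42,-1.0844,-2.1828,0
CG,X,C,C1',-5.4711,2.1801,0
CG,X,C,C2',-5.4103,3.4668,-0.55
CG,X,C,O2',-4.2764,4.2409,-0.75
CG,X,C,HO2',-4.2026,5.1882,-0.95
CG,X,C,C3',-6.5043,4.0714,-0.3
CG,X,C,O3',-6.4647,5.3795,0.25
CG,X,C,O4',-6.7587,1.9863,0.4
CG,X,C,C4',-7.4973,3.1555,0.45
CG,X,C,C5',-8.6648,2.9118,1.3
CG,X,C,O5',-8.6253,4.1845,-0.15
CG,X,C,P,-8.302,5.7391,-2
CG,X,C,OP1,-8.7997,4.8922,-0.9
CG,X,C,OP2,-9.6793,6.2032,-2.55
CG,Y,G,N1,0.5743,0.2434,0
CG,Y,G,C2,1.1819,1.4935,0
CG,Y,G,N3,2.5684,1.5924,0
CG,Y,G,C4,3.3472,0.4411,0
CG,Y,G,C5,2.7396,-0.809,0
CG,Y,G,C6,1.3531,-0.9079,0
CG,Y,G,N9,4.724,0.2496,0
CG,Y,G,C8,4.9672,-1.119,0
CG,Y,G,N7,3.7408,-1.7732,0
CG,Y,G,O6,0.8155,-2.0142,0
CG,Y,G,N2,0.431,2.6034,0
CG,Y,G,H1,-0.4332,0.1715,0
CG,Y,G,H21,0.8725,3.5118,0
CG,Y,G,H22,-0.5764,2.5316,0
CG,Y,G,C1',6.1955,0.4078,0
CG,Y,G,C2',6.9589,1.4454,0.55
CG,Y,G,O2',6.5659,2.761,0.75
CG,Y,G,HO2',7.1054,3.5431,0.95
CG,Y,G,C3',8.1894,1.2258,0.3
CG,Y,G,O3',8.9827,2.2666,-0.25
CG,Y,G,O4',7.0734,-0.5538,-0.4
CG,Y,G,C4',8.3835,-0.1111,-0.45
CG,Y,G,C5',9.1368,-1.0359,-1.3
CG,Y,G,O5',9.9078,-0.0226,0.15
CG,Y,G,P,10.6361,1.3884,2
CG,Y,G,OP1,10.4891,0.4171,0.9
CG,Y,G,OP2,11.9981,0.8811,2.55
UA,X,U,N1,-4.4694,1.0691,0
UA,X,U,C2,-3.0899,1.2398,0
UA,X,U,N3,-2.2523,0.1305,0
UA,X,U,C4,-2.7941,-1.1495,0
UA,X,U,C5,-4.1736,-1.3203,0
UA,X,U,C6,-5.0112,-0.211,0
UA,X,U,O2,-2.6104,2.3725,0
UA,X,U,O4,-2.0529,-2.1311,0
UA,X,U,H3,-1.2499,0.2546,0
UA,X,U,C1',-5.5588,2.0708,0
UA,X,U,C2',-5.5562,3.359,-0.55
UA,X,U,O2',-4.4584,4.1835,-0.75
UA,X,U,HO2',-4.4275,5.1332,-0.95
UA,X,U,C3',-6.6764,3.9136,-0.3
UA,X,U,O3',-6.6959,5.2221,0.25
UA,X,U,O4',-6.8363,1.8191,0.4
UA,X,U,C4',-7.627,2.9537,0.45
UA,X,U,C5',-8.7823,2.6575,1.3
UA,X,U,O5',-8.8003,3.9307,-0.15
UA,X,U,P,-8.5476,5.4983,-2
UA,X,U,OP1,-9.0066,4.6298,-0.9
UA,X,U,OP2,-9.9445,5.8997,-2.55
UA,Y,A,N1,0.6152,0.4808,0
UA,Y,A,C2,1.2025,1.7407,0
UA,Y,A,N3,2.5872,1.8619,0
UA,Y,A,C4,3.3846,0.7234,0
UA,Y,A,C5,2.7973,-0.5364,0
UA,Y,A,C6,1.4126,-0.6577,0
UA,Y,A,N9,4.7643,0.5541,0
UA,Y,A,C8,5.0296,-0.8103,0
UA,Y,A,N7,3.814,-1.4843,0
UA,Y,A,N6,0.8464,-1.8722,0
UA,Y,A,H61,-0.1597,-1.9604,0
UA,Y,A,H62,1.4258,-2.6995,0
UA,Y,A,C1',6.1961,0.9286,0
UA,Y,A,C2',6.7975,2.0678,0.55
UA,Y,A,O2',6.214,3.3106,0.75
UA,Y,A,HO2',6.6317,4.1641,0.95
UA,Y,A,C3',8.047,2.0328,0.3
UA,Y,A,O3',8.6773,3.1796,-0.25
UA,Y,A,O4',7.2067,0.1076,-0.4
UA,Y,A,C4',8.4369,0.7394,-0.45
UA,Y,A,C5',9.3188,-0.0636,-1.3
UA,Y,A,O5',9.9313,1.0527,0.15
UA,Y,A,P,10.4425,2.556,2
UA,Y,A,OP1,10.441,1.5736,0.9
UA,Y,A,OP2,11.8647,2.256,2.55
AUHG,X,A,N1,-3.7087,1.6559,0
AUHG,X,A,C2,-4.6181,0.6047,0
AUHG,X,A,N3,-4.1624,-0.7085,0
AUHG,X,A,C4,-2.7973,-0.9705,0
AUHG,X,A,C5,-1.8879,0.0808,0
AUHG,X,A,C6,-2.3436,1.394,0
AUHG,X,A,N9,-2.0786,-2.1602,0
AUHG,X,A,C8,-0.725,-1.8443,0
AUHG,X,A,N7,-0.6071,-0.4593,0
AUHG,X,A,N6,-1.4669,2.4074,0
AUHG,X,A,H61,-1.798,3.3615,0
AUHG,X,A,H62,-0.475,2.217,0
AUHG,X,A,C1',-1.8347,-3.62,0
AUHG,X,A,C2',-2.6283,-4.6346,-0.55
AUHG,X,A,O2',-4.001,-4.6106,-0.75
AUHG,X,A,HO2',-4.609,-5.3408,-0.95
AUHG,X,A,C3',-2.0853,-5.7605,-0.3
AUHG,X,A,O3',-2.874,-6.8048,0.25
AUHG,X,A,O4',-0.6721,-4.2064,0.4
AUHG,X,A,C4',-0.7455,-5.5874,0.45
AUHG,X,A,C5',0.3479,-6.0636,1.3
AUHG,X,A,O5',-0.4202,-7.0791,-0.15
AUHG,X,A,P,-1.5828,-8.1606,-2
AUHG,X,A,OP1,-0.687,-7.7574,-0.9
AUHG,X,A,OP2,-0.7275,-9.3356,-2.55
AUHG,Y,U,N1,4.2498,-1.0266,0
AUHG,Y,U,C2,2.8773,-1.2468,0
AUHG,Y,U,N3,2.0004,-0.1683,0
AUHG,Y,U,C4,2.4959,1.1303,0
AUHG,Y,U,C5,3.8683,1.3506,0
AUHG,Y,U,C6,4.7453,0.2721,0
AUHG,Y,U,O2,2.4389,-2.396,0
AUHG,Y,U,O4,1.7199,2.0847,0
AUHG,Y,U,H3,1.0031,-0.3284,0
AUHG,Y,U,C1',5.3745,-1.9885,0
AUHG,Y,U,C2',5.4182,-3.2759,-0.55
AUHG,Y,U,O2',4.3508,-4.1394,-0.75
AUHG,Y,U,HO2',4.354,-5.0896,-0.95
AUHG,Y,U,C3',6.5577,-3.7899,-0.3
AUHG,Y,U,O3',6.6242,-5.0968,0.25
AUHG,Y,U,O4',6.6422,-1.691,0.4
AUHG,Y,U,C4',7.4731,-2.7964,0.45
AUHG,Y,U,C5',8.6171,-2.4589,1.3
AUHG,Y,U,O5',8.6808,-3.7306,-0.15
AUHG,Y,U,P,8.4846,-5.3063,-2
AUHG,Y,U,OP1,8.9121,-4.4218,-0.9
AUHG,Y,U,OP2,9.8951,-5.6572,-2.55
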