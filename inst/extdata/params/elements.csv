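element,radius,eps,haselP,class
H,1.20,0.020,0.939,hydrogen
H.polar,0.50,0.010,0.939,hydrogen
C,1.70,0.150,1.546,apolar
N,1.55,0.160,1.484,polar
O,1.52,0.160,0.993,polar
S,1.80,0.200,1.121,polar
P,1.80,0.200,1.200,polar
F,1.47,0.130,1.200,apolar
Cl,1.75,0.240,1.200,apolar
Br,1.85,0.300,1.200,apolar
I,1.98,0.350,1.200,apolar
Na,2.27,0.200,1.200,metal
K,2.75,0.200,1.200,metal
Mg,1.73,0.200,1.200,metal
Ca,2.31,0.200,1.200,metal
Zn,1.39,0.200,1.200,metal
Fe,1.45,0.200,1.200,metal
Mn,1.45,0.200,1.200,metal
*,1.70,0.150,1.200,other
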