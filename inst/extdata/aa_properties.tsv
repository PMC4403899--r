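# prostab amino-acid property table v1
# mass: average free amino-acid mass (Da); hydrophilicity: Hopp-Woods scale;
# pi: isoelectric point of the free amino acid (pH units)
aa	mass	hydrophilicity	pi
A	89.09	-0.5	6.00
R	174.20	3.0	10.76
N	132.12	0.2	5.41
D	133.10	3.0	2.77
C	121.16	-1.0	5.07
Q	146.15	0.2	5.65
E	147.13	3.0	3.22
G	75.07	0.0	5.97
H	155.16	-0.5	7.59
I	131.17	-1.8	6.02
L	131.17	-1.8	5.98
K	146.19	3.0	9.74
M	149.21	-1.3	5.74
F	165.19	-2.5	5.48
P	115.13	0.0	6.30
S	105.09	0.3	5.68
T	119.12	-0.4	5.60
W	204.23	-3.4	5.89
Y	181.19	-2.3	5.66
V	117.15	-1.5	5.96
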