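# prostab residue-sphere ASA reference v1
# radius: effective side-chain sphere radius at CB (A);
# max_asa: surface area of the isolated probe-inflated sphere (A^2), probe 1.4 A
aa	radius	max_asa
A	1.9	136.8478
R	3.3	277.5911
N	2.5	191.1345
D	2.5	191.1345
C	2.2	162.8602
Q	2.8	221.6708
E	2.8	221.6708
G	1.7	120.7628
H	2.9	232.3522
I	2.7	211.2407
L	2.7	211.2407
K	3.0	243.2849
M	2.9	232.3522
F	3.1	254.4690
P	2.3	172.0336
S	2.0	145.2672
T	2.2	162.8602
W	3.5	301.7186
Y	3.3	277.5911
V	2.4	181.4584
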