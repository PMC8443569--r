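residue	polarity	hydropathy
A	nonpolar	neutral
R	charged	hydrophilic
N	polar	hydrophilic
D	charged	hydrophilic
C	polar	hydrophobic
Q	polar	hydrophilic
E	charged	hydrophilic
G	nonpolar	neutral
H	charged	hydrophilic
I	nonpolar	hydrophobic
L	nonpolar	hydrophobic
K	charged	hydrophilic
M	nonpolar	neutral
F	nonpolar	hydrophobic
P	nonpolar	neutral
S	polar	neutral
T	polar	neutral
W	nonpolar	neutral
Y	polar	neutral
V	nonpolar	hydrophobic
X	unknown	unknown
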