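# Nearest-neighbor helix stack free energies, 37 C, kcal/mol.
# Turner 2004 values rounded to 0.1 kcal/mol; Watson-Crick and G-U wobble pairs.
# Step AB/CD denotes 5'-A B-3' over 3'-C D-5' with pairs A-C (outer) and B-D (inner).
# Symmetry: E(AB/CD) = E(DC/BA).
step	energy
CG/GC	-2.4
CC/GG	-3.3
CU/GG	-2.1
CG/GU	-1.4
CU/GA	-2.1
CA/GU	-2.1
GG/CC	-3.3
GC/CG	-3.4
GU/CG	-2.5
GG/CU	-1.5
GU/CA	-2.2
GA/CU	-2.4
GG/UC	-2.1
GC/UG	-2.5
GU/UG	1.3
GG/UU	-0.5
GU/UA	-1.4
GA/UU	-1.3
UG/GC	-1.4
UC/GG	-1.5
UU/GG	-0.5
UG/GU	0.3
UU/GA	-0.6
UA/GU	-1.0
AG/UC	-2.1
AC/UG	-2.2
AU/UG	-1.4
AG/UU	-0.6
AU/UA	-1.1
AA/UU	-0.9
UG/AC	-2.1
UC/AG	-2.4
UU/AG	-1.3
UG/AU	-1.0
UU/AA	-0.9
UA/AU	-1.3
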