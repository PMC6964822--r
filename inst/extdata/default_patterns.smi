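# Default predefined substructure patterns: common functional groups and
# ring systems, one SMILES per line. Users working with a dedicated
# fingerprint-derived substructure list should supply their own file.
# hydrocarbon chains
CC
CCC
CCCC
CCCCC
CCCCCC
CCCCCCCC
C=C
C=CC
C#C
C#CC
# oxygen functions
CO
CCO
C=O
CC=O
OC=O
CC(=O)O
COC
CC(C)O
OCC(O)CO
C(=O)OC
c1ccccc1O
Cc1ccc(O)cc1
OC(=O)c1ccccc1
# nitrogen functions
CN
CCN
CNC
CC(N)C(=O)O
NC=O
CNC=O
CC(=O)N
C#N
NCC
Nc1ccccc1
CNc1ccccc1
C1CCNCC1
C1CCNC1
n1ccccc1
c1cc[nH]c1
# aromatic and fused ring systems
c1ccccc1
Cc1ccccc1
CCc1ccccc1
c1ccc2ccccc2c1
c1ccc2[nH]ccc2c1
c1ccc2ncccc2c1
C1CCCCC1
C1CCCC1
C1CCC2CCCCC2C1
O=C1CCCCC1
C1CCOC1
c1ccoc1
c1ccsc1
# sulfur and halogens
CS
CSC
S=O
OS(=O)=O
CCl
CBr
CF
Clc1ccccc1
Fc1ccccc1
# phosphate
OP(=O)(O)O
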