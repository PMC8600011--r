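residue,atom,classes
ALA,N,donor
ALA,CA,neutral
ALA,C,neutral
ALA,O,acceptor
ALA,CB,hydrophobic
ARG,N,donor
ARG,CA,neutral
ARG,C,neutral
ARG,O,acceptor
ARG,CB,hydrophobic
ARG,CG,hydrophobic
ARG,CD,hydrophobic
ARG,NE,positive|donor
ARG,CZ,positive
ARG,NH1,positive|donor
ARG,NH2,positive|donor
ASN,N,donor
ASN,CA,neutral
ASN,C,neutral
ASN,O,acceptor
ASN,CB,hydrophobic
ASN,CG,neutral
ASN,OD1,acceptor
ASN,ND2,donor
ASP,N,donor
ASP,CA,neutral
ASP,C,neutral
ASP,O,acceptor
ASP,CB,hydrophobic
ASP,CG,neutral
ASP,OD1,negative|acceptor
ASP,OD2,negative|acceptor
CYS,N,donor
CYS,CA,neutral
CYS,C,neutral
CYS,O,acceptor
CYS,CB,hydrophobic
CYS,SG,donor|acceptor
GLN,N,donor
GLN,CA,neutral
GLN,C,neutral
GLN,O,acceptor
GLN,CB,hydrophobic
GLN,CG,hydrophobic
GLN,CD,neutral
GLN,OE1,acceptor
GLN,NE2,donor
GLU,N,donor
GLU,CA,neutral
GLU,C,neutral
GLU,O,acceptor
GLU,CB,hydrophobic
GLU,CG,hydrophobic
GLU,CD,neutral
GLU,OE1,negative|acceptor
GLU,OE2,negative|acceptor
GLY,N,donor
GLY,CA,neutral
GLY,C,neutral
GLY,O,acceptor
HIS,N,donor
HIS,CA,neutral
HIS,C,neutral
HIS,O,acceptor
HIS,CB,hydrophobic
HIS,CG,aromatic
HIS,ND1,aromatic|positive|donor|acceptor
HIS,CD2,aromatic
HIS,CE1,aromatic
HIS,NE2,aromatic|positive|donor|acceptor
ILE,N,donor
ILE,CA,neutral
ILE,C,neutral
ILE,O,acceptor
ILE,CB,hydrophobic
ILE,CG1,hydrophobic
ILE,CG2,hydrophobic
ILE,CD1,hydrophobic
LEU,N,donor
LEU,CA,neutral
LEU,C,neutral
LEU,O,acceptor
LEU,CB,hydrophobic
LEU,CG,hydrophobic
LEU,CD1,hydrophobic
LEU,CD2,hydrophobic
LYS,N,donor
LYS,CA,neutral
LYS,C,neutral
LYS,O,acceptor
LYS,CB,hydrophobic
LYS,CG,hydrophobic
LYS,CD,hydrophobic
LYS,CE,hydrophobic
LYS,NZ,positive|donor
MET,N,donor
MET,CA,neutral
MET,C,neutral
MET,O,acceptor
MET,CB,hydrophobic
MET,CG,hydrophobic
MET,SD,acceptor
MET,CE,hydrophobic
PHE,N,donor
PHE,CA,neutral
PHE,C,neutral
PHE,O,acceptor
PHE,CB,hydrophobic
PHE,CG,aromatic
PHE,CD1,aromatic
PHE,CD2,aromatic
PHE,CE1,aromatic
PHE,CE2,aromatic
PHE,CZ,aromatic
PRO,N,neutral
PRO,CA,neutral
PRO,C,neutral
PRO,O,acceptor
PRO,CB,hydrophobic
PRO,CG,hydrophobic
PRO,CD,hydrophobic
SER,N,donor
SER,CA,neutral
SER,C,neutral
SER,O,acceptor
SER,CB,hydrophobic
SER,OG,donor|acceptor
THR,N,donor
THR,CA,neutral
THR,C,neutral
THR,O,acceptor
THR,CB,hydrophobic
THR,OG1,donor|acceptor
THR,CG2,hydrophobic
TRP,N,donor
TRP,CA,neutral
TRP,C,neutral
TRP,O,acceptor
TRP,CB,hydrophobic
TRP,CG,aromatic
TRP,CD1,aromatic
TRP,CD2,aromatic
TRP,NE1,aromatic|donor
TRP,CE2,aromatic
TRP,CE3,aromatic
TRP,CZ2,aromatic
TRP,CZ3,aromatic
TRP,CH2,aromatic
TYR,N,donor
TYR,CA,neutral
TYR,C,neutral
TYR,O,acceptor
TYR,CB,hydrophobic
TYR,CG,aromatic
TYR,CD1,aromatic
TYR,CD2,aromatic
TYR,CE1,aromatic
TYR,CE2,aromatic
TYR,CZ,aromatic
TYR,OH,donor|acceptor
VAL,N,donor
VAL,CA,neutral
VAL,C,neutral
VAL,O,acceptor
VAL,CB,hydrophobic
VAL,CG1,hydrophobic
VAL,CG2,hydrophobic
ALA,OXT,acceptor
ARG,OXT,acceptor
ASN,OXT,acceptor
ASP,OXT,acceptor
CYS,OXT,acceptor
GLN,OXT,acceptor
GLU,OXT,acceptor
GLY,OXT,acceptor
HIS,OXT,acceptor
ILE,OXT,acceptor
LEU,OXT,acceptor
LYS,OXT,acceptor
MET,OXT,acceptor
PHE,OXT,acceptor
PRO,OXT,acceptor
SER,OXT,acceptor
THR,OXT,acceptor
TRP,OXT,acceptor
TYR,OXT,acceptor
VAL,OXT,acceptor
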