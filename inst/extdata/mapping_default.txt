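# Default residue -> CG site mapping (reconstruction; user-overridable).
# One sidechain site per line:
#   residue  site_index  site_type  parent  nH  atoms
# parent = 0 means bonded to the backbone (C-alpha) site; otherwise the
# site_index of the sidechain site it hangs off. nH counts hydrogens attached
# to the member heavy atoms (standard protonation at pH 7).
# The backbone site is implicit: the C-alpha atom alone, for position, force
# and mass bookkeeping alike.
GLY 1 apolar   0 0 -
ALA 1 apolar   0 3 CB
SER 1 polar    0 3 CB,OG
CYS 1 polar    0 3 CB,SG
THR 1 polar    0 5 CB,OG1,CG2
VAL 1 apolar   0 7 CB,CG1,CG2
LEU 1 apolar   0 3 CB,CG
LEU 2 apolar   1 6 CD1,CD2
ILE 1 apolar   0 3 CB,CG1
ILE 2 apolar   1 6 CG2,CD1
MET 1 apolar   0 4 CB,CG
MET 2 polar    1 3 SD,CE
PRO 1 apolar   0 6 CB,CG,CD
PHE 1 apolar   0 2 CB,CG
PHE 2 apolar   1 2 CD1,CE1
PHE 3 apolar   1 3 CD2,CE2,CZ
TRP 1 apolar   0 2 CB,CG,CD2
TRP 2 polar    1 2 CD1,NE1,CE2
TRP 3 apolar   1 2 CE3,CZ3
TRP 4 apolar   2 2 CZ2,CH2
TYR 1 apolar   0 2 CB,CG
TYR 2 apolar   1 2 CD1,CE1
TYR 3 apolar   1 2 CD2,CE2
TYR 4 polar    2 1 CZ,OH
ASP 1 apolar   0 2 CB
ASP 2 negative 1 0 CG,OD1,OD2
GLU 1 apolar   0 4 CB,CG
GLU 2 negative 1 0 CD,OE1,OE2
ASN 1 apolar   0 2 CB
ASN 2 polar    1 2 CG,OD1,ND2
GLN 1 apolar   0 4 CB,CG
GLN 2 polar    1 2 CD,OE1,NE2
LYS 1 apolar   0 6 CB,CG,CD
LYS 2 positive 1 5 CE,NZ
ARG 1 apolar   0 6 CB,CG,CD
ARG 2 positive 1 1 NE,CZ
ARG 3 positive 2 4 NH1,NH2
HIS 1 apolar   0 2 CB
HIS 2 polar    1 1 CG,ND1
HIS 3 polar    2 2 CD2,NE2,CE1
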