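# Per-residue relative dielectric constants (dimensionless).
# Flat default table: eps = 4 for every standard residue, a typical
# protein-interior value. Edit or supply your own two-column file
# (RESNAME eps) to encode residue-specific polarizabilities.
ALA 4
ARG 4
ASN 4
ASP 4
CYS 4
GLN 4
GLU 4
GLY 4
HIS 4
ILE 4
LEU 4
LYS 4
MET 4
PHE 4
PRO 4
SER 4
THR 4
TRP 4
TYR 4
VAL 4
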