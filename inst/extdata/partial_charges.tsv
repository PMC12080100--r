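# Simplified CHARMM-flavoured partial charges for the atom set produced by
# the synthetic structure builder. "*" rows apply to any residue type.
residue_type	atom_name	charge
*	N	-0.47
*	H	0.31
*	CA	0.07
*	HA	0.09
*	C	0.51
*	O	-0.51
*	CB	-0.18
ARG	CG	-0.18
ASN	CG	0.55
ASP	CG	0.62
CYS	SG	-0.23
GLN	CG	-0.18
GLU	CG	-0.28
HIS	CG	-0.05
ILE	CG1	-0.18
LEU	CG	-0.09
LYS	CG	-0.18
MET	CG	-0.14
PHE	CG	0.00
PRO	CG	-0.18
SER	OG	-0.66
THR	OG1	-0.66
TRP	CG	-0.03
TYR	CG	0.00
VAL	CG1	-0.27
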