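# Backbone-independent rotamer library: modal chi values (degrees) with
# prior frequencies. Frequencies sum to 1 within each amino acid.
# NA marks chi angles the amino acid does not have.
aa3	chi1	chi2	chi3	chi4	freq
SER	62	NA	NA	NA	0.30
SER	-65	NA	NA	NA	0.40
SER	180	NA	NA	NA	0.30
CYS	-65	NA	NA	NA	0.50
CYS	180	NA	NA	NA	0.26
CYS	62	NA	NA	NA	0.24
THR	62	NA	NA	NA	0.45
THR	-60	NA	NA	NA	0.43
THR	180	NA	NA	NA	0.12
VAL	175	NA	NA	NA	0.60
VAL	-64	NA	NA	NA	0.25
VAL	63	NA	NA	NA	0.15
LEU	-65	175	NA	NA	0.60
LEU	177	65	NA	NA	0.30
LEU	-85	65	NA	NA	0.10
ILE	-65	170	NA	NA	0.60
ILE	-57	-60	NA	NA	0.15
ILE	62	170	NA	NA	0.15
ILE	180	165	NA	NA	0.10
MET	-65	-65	-70	NA	0.35
MET	-65	180	75	NA	0.25
MET	180	180	180	NA	0.25
MET	-65	180	180	NA	0.15
PHE	-65	90	NA	NA	0.45
PHE	180	80	NA	NA	0.35
PHE	62	90	NA	NA	0.20
TYR	-65	90	NA	NA	0.45
TYR	180	80	NA	NA	0.35
TYR	62	90	NA	NA	0.20
TRP	-65	95	NA	NA	0.35
TRP	180	-105	NA	NA	0.25
TRP	-65	-5	NA	NA	0.20
TRP	62	-90	NA	NA	0.20
ASP	-70	-15	NA	NA	0.50
ASP	180	15	NA	NA	0.30
ASP	62	-10	NA	NA	0.20
ASN	-65	-20	NA	NA	0.45
ASN	180	30	NA	NA	0.30
ASN	62	-75	NA	NA	0.25
GLU	-65	180	-10	NA	0.40
GLU	180	180	0	NA	0.35
GLU	-65	-65	-40	NA	0.25
GLN	-65	180	-25	NA	0.40
GLN	180	180	20	NA	0.35
GLN	-65	-65	-40	NA	0.25
LYS	-65	180	180	180	0.40
LYS	180	180	180	180	0.35
LYS	-65	-65	180	180	0.25
ARG	-65	180	180	180	0.30
ARG	180	180	180	180	0.25
ARG	-65	-65	180	180	0.20
ARG	62	180	180	180	0.15
ARG	180	65	180	180	0.10
HIS	-65	-70	NA	NA	0.40
HIS	180	60	NA	NA	0.35
HIS	62	-75	NA	NA	0.25
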