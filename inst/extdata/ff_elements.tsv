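# Per-element force-field parameters (heavy atoms only).
# columns: element, vdW radius (Angstrom), LJ well depth (eu),
#          solvation sigma (eu per Angstrom^2 of buried area;
#          negative = burial favorable)
element	radius	well_depth	sigma_solv
C	1.70	0.12	-0.025
N	1.55	0.16	0.015
O	1.52	0.20	0.015
S	1.80	0.25	-0.025
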