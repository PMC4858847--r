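# spanfold nearest-neighbour parameter set (free energies, kcal/mol, 37 C)
# STACK <outer pair> <inner pair> <dG>: helix stacking, outer pair (k,l)
#   stacked on inner pair (k+1, l-1); table satisfies the thermodynamic
#   symmetry dG[P][Q] = dG[rev Q][rev P].
# HAIRPIN/BULGE/INTERNAL <length> <dG>: length-dependent loop initiation;
#   lengths beyond the table are extended logarithmically (1.75 RT ln(l/30)).
# MULTI: affine multiloop coefficients. MISC terminal_au: simplified
#   terminal non-CG pair penalty (applied only with dangle_mode "simplified").
STACK	AU	AU	-0.93
STACK	AU	UA	-1.10
STACK	AU	CG	-2.24
STACK	AU	GC	-2.08
STACK	AU	GU	-0.55
STACK	AU	UG	-1.36
STACK	UA	AU	-1.33
STACK	UA	UA	-0.93
STACK	UA	CG	-2.35
STACK	UA	GC	-2.11
STACK	UA	GU	-1.00
STACK	UA	UG	-1.27
STACK	CG	AU	-2.11
STACK	CG	UA	-2.08
STACK	CG	CG	-3.26
STACK	CG	GC	-2.36
STACK	CG	GU	-1.41
STACK	CG	UG	-2.11
STACK	GC	AU	-2.35
STACK	GC	UA	-2.24
STACK	GC	CG	-3.42
STACK	GC	GC	-3.26
STACK	GC	GU	-1.53
STACK	GC	UG	-2.51
STACK	GU	AU	-1.27
STACK	GU	UA	-1.36
STACK	GU	CG	-2.51
STACK	GU	GC	-2.11
STACK	GU	GU	-0.50
STACK	GU	UG	1.29
STACK	UG	AU	-1.00
STACK	UG	UA	-0.55
STACK	UG	CG	-1.53
STACK	UG	GC	-1.41
STACK	UG	GU	-0.30
STACK	UG	UG	-0.50
HAIRPIN	3	5.40
HAIRPIN	4	5.60
HAIRPIN	5	5.70
HAIRPIN	6	5.40
HAIRPIN	7	6.00
HAIRPIN	8	5.50
HAIRPIN	9	6.40
HAIRPIN	10	6.50
HAIRPIN	11	6.60
HAIRPIN	12	6.70
HAIRPIN	13	6.80
HAIRPIN	14	6.90
HAIRPIN	15	6.90
HAIRPIN	16	7.00
HAIRPIN	17	7.10
HAIRPIN	18	7.10
HAIRPIN	19	7.20
HAIRPIN	20	7.20
HAIRPIN	21	7.30
HAIRPIN	22	7.30
HAIRPIN	23	7.40
HAIRPIN	24	7.40
HAIRPIN	25	7.50
HAIRPIN	26	7.50
HAIRPIN	27	7.50
HAIRPIN	28	7.60
HAIRPIN	29	7.60
HAIRPIN	30	7.70
BULGE	1	3.80
BULGE	2	2.80
BULGE	3	3.20
BULGE	4	3.60
BULGE	5	4.00
BULGE	6	4.40
BULGE	7	4.59
BULGE	8	4.70
BULGE	9	4.80
BULGE	10	4.90
BULGE	11	5.00
BULGE	12	5.10
BULGE	13	5.19
BULGE	14	5.27
BULGE	15	5.34
BULGE	16	5.40
BULGE	17	5.46
BULGE	18	5.52
BULGE	19	5.58
BULGE	20	5.62
BULGE	21	5.67
BULGE	22	5.71
BULGE	23	5.75
BULGE	24	5.79
BULGE	25	5.83
BULGE	26	5.87
BULGE	27	5.90
BULGE	28	5.93
BULGE	29	5.96
BULGE	30	6.00
INTERNAL	2	1.50
INTERNAL	3	1.60
INTERNAL	4	1.70
INTERNAL	5	1.80
INTERNAL	6	2.00
INTERNAL	7	2.20
INTERNAL	8	2.30
INTERNAL	9	2.40
INTERNAL	10	2.50
INTERNAL	11	2.60
INTERNAL	12	2.70
INTERNAL	13	2.80
INTERNAL	14	2.90
INTERNAL	15	3.00
INTERNAL	16	3.10
INTERNAL	17	3.10
INTERNAL	18	3.20
INTERNAL	19	3.30
INTERNAL	20	3.40
INTERNAL	21	3.40
INTERNAL	22	3.50
INTERNAL	23	3.50
INTERNAL	24	3.60
INTERNAL	25	3.60
INTERNAL	26	3.70
INTERNAL	27	3.70
INTERNAL	28	3.80
INTERNAL	29	3.80
INTERNAL	30	3.90
MULTI	closing	3.40
MULTI	branch	0.40
MULTI	unpaired	0.00
MISC	terminal_au	0.50
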