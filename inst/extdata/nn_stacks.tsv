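# Nearest-neighbor helix stack free energies, kcal/mol at 37 C.
# pair1 = 5' base of the outer pair then its partner (seq[i], seq[j]);
# pair2 = the stacked pair one step inward (seq[i+1], seq[j-1]).
# Values are Turner-2004-style Watson-Crick and G:U wobble stacks.
pair1	pair2	dG
AU	AU	-0.93
AU	CG	-2.24
AU	GC	-2.08
AU	GU	-0.55
AU	UA	-1.1
AU	UG	-1.36
CG	AU	-2.11
CG	CG	-3.26
CG	GC	-2.36
CG	GU	-1.41
CG	UA	-2.08
CG	UG	-2.11
GC	AU	-2.35
GC	CG	-3.42
GC	GC	-3.26
GC	GU	-1.53
GC	UA	-2.24
GC	UG	-2.51
GU	AU	-1.27
GU	CG	-2.51
GU	GC	-2.11
GU	GU	-0.5
GU	UA	-1.36
GU	UG	1.29
UA	AU	-1.33
UA	CG	-2.35
UA	GC	-2.11
UA	GU	-1
UA	UA	-0.93
UA	UG	-1.27
UG	AU	-1
UG	CG	-1.53
UG	GC	-1.41
UG	GU	0.3
UG	UA	-0.55
UG	UG	-0.5
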