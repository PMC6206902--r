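# Nearest-neighbour RNA/RNA stacking free energies, kcal/mol at 37 C.
# Key XY/WZ: target strand 5'-XY-3' on top, miRNA strand 3'-WZ-5' below,
# so column pairs are X:W and Y:Z. Watson-Crick values are the standard
# nearest-neighbour set; G:U wobble stacks are a representative reduced set
# (unlisted wobble contexts fall back to the model's default stack term).
stack	dg
AA/UU	-0.93
UU/AA	-0.93
AU/UA	-1.10
UA/AU	-1.33
CU/GA	-2.08
AG/UC	-2.08
CA/GU	-2.11
UG/AC	-2.11
GU/CA	-2.24
AC/UG	-2.24
GA/CU	-2.35
UC/AG	-2.35
CG/GC	-2.36
GG/CC	-3.26
CC/GG	-3.26
GC/CG	-3.42
GG/UC	-1.50
GA/UU	-1.30
AG/UU	-0.55
UG/GC	-1.40
GU/UA	-1.20
UU/GA	-1.00
CG/GU	-1.40
GC/UG	-1.50
GU/UG	-0.50
UG/GU	-0.60
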