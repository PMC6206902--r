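# Curated osteogenesis-related genes (symbols as used in rodent studies).
# Stand-in for interactive disease-gene databases in the core-gene funnel.
Vdr
Mgp
Fabp3
Fst
Cd38
Col1a1
Col1a2
Runx2
Sp7
Alpl
Bglap
Spp1
Ibsp
Bmp2
Bmp4
Bmp7
Sparc
Tnfsf11
Tnfrsf11b
Ctsk
Sost
Dlx5
Msx2
Wnt3a
Ctnnb1
Lrp5
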