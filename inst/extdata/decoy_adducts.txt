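# Implausible single-element decoy adducts (default universe).
# One adduct per line; override via read_adduct_list().
+He
+Li
+Be
+B
+F
+Al
+Si
+P
+Cl
+Sc
+Ti
+V
+Cr
+Mn
+Fe
+Co
+Ni
+Cu
+Zn
+Ga
+Ge
+As
+Se
+Br
+Rb
+Sr
+Y
+Zr
+Nb
+Mo
+Ru
+Rh
+Pd
+Ag
+Cd
+In
+Sn
+Sb
+Te
+I
+Cs
+Ba
+La
+Ce
+Pr
+Nd
+Sm
+Eu
+Gd
+Tb
+Dy
+Ho
+Er
+Tm
+Yb
+Lu
+Hf
+Ta
+W
+Re
+Os
+Ir
+Pt
+Au
+Hg
+Tl
+Pb
+Bi
+Th
+U
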