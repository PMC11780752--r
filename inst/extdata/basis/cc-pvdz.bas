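# Correlation-consistent double-zeta (cc-pVDZ) set, Cartesian (6d)
# convention.  Exponents follow the standard published tabulation.  The
# nitrogen general-contraction coefficients are regenerated with the
# package's spherically averaged atomic Hartree-Fock in the primitive
# basis (documented in the methods vignette); molecular energies agree
# with the published contraction to a few mHartree.  The hydrogen block
# is the published data.
element H
S
  13.01000000   0.01968500
   1.96200000   0.13797700
   0.44460000   0.47814800
   0.12200000   0.50124000
S
   0.12200000   1.00000000
P
   0.72700000   1.00000000
end
element N
S
9046.00000000   0.00070347
1357.00000000   0.00534832
 309.30000000   0.02773544
  87.73000000   0.10140581
  28.56000000   0.28991024
   9.46400000   0.49486444
   3.30000000   0.23037218
   0.65880000   0.00426599
   0.20330000   0.00016481
S
9046.00000000  -0.00015496
1357.00000000  -0.00123230
 309.30000000  -0.00606674
  87.73000000  -0.02503454
  28.56000000  -0.06964352
   9.46400000  -0.18891879
   3.30000000  -0.08284734
   0.65880000   0.65489591
   0.20330000   0.46416205
S
   0.20330000   1.00000000
P
  13.55000000   0.03653689
   2.91700000   0.20189851
   0.79730000   0.44260208
   0.21850000   0.54870300
P
   0.21850000   1.00000000
D
   0.81700000   1.00000000
end
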