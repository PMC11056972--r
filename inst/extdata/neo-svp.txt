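! neo-svp: package-defined (synthetic) split-valence-plus-polarization
! electronic sets for the bundled fixtures: even-tempered 5s (ratio 3.4)
! plus one p function per atom.  Not a published standard basis.
H 0
S 1 1.00
    0.07000000    1.0
S 1 1.00
    0.23800000    1.0
S 1 1.00
    0.80920000    1.0
S 1 1.00
    2.75128000    1.0
S 1 1.00
    9.35435200    1.0
P 1 1.00
    0.80000000    1.0
****
He 0
S 1 1.00
    0.22000000    1.0
S 1 1.00
    0.74800000    1.0
S 1 1.00
    2.54320000    1.0
S 1 1.00
    8.64688000    1.0
S 1 1.00
   29.39939200    1.0
P 1 1.00
    0.80000000    1.0
****
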