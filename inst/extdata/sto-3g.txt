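! STO-3G minimal electronic basis (standard published exponents and
! contraction coefficients) for the elements used by the bundled fixtures.
H 0
S 3 1.00
    3.42525091    0.15432897
    0.62391373    0.53532814
    0.16885540    0.44463454
****
He 0
S 3 1.00
    6.36242139    0.15432897
    1.15892300    0.53532814
    0.31364979    0.44463454
****
O 0
S 3 1.00
  130.70932000    0.15432897
   23.80886100    0.53532814
    6.44360830    0.44463454
SP 3 1.00
    5.03315130   -0.09996723    0.15591627
    1.16959610    0.39951283    0.60768372
    0.38038900    0.70011547    0.39195739
****
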