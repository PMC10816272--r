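# Default structural-alert (REOS-style) patterns: reactive, toxic or
# assay-interfering substructures.  Extend freely; names must be unique.
nitro: "[$([N+](=O)[O-]),$(N(=O)=O)]"
acyl_halide: "[CX3](=O)[F,Cl,Br,I]"
aldehyde: "[CX3H1]=O"
epoxide_aziridine: "[C;r3]1[O,N;r3][C;r3]1"
isocyanate: "N=C=O"
thiol: "[SX2H]"
peroxide: "[OX2][OX2]"
alkyl_halide_reactive: "[CH2X4][Br,I]"
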