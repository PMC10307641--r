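A1CF
BOLL
ELAVL4
MSI1
KHDRBS3
PABPC5
RBM4B
TIA1
EIF4G2
RBFOX3
BRUNOL6
RBM23
SRSF8
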