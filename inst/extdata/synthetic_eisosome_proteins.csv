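gene
PIL1
LSP1
SLM1
SLM2
SEG1
SEG2
NCE102
FHN1
EIS1
MDG1
MSC3
PKH1
PKH2
YGR130C
INP51
INP52
PST2
RFS1
YCP4
TOS7
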