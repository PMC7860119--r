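gene
LSP1
SLM1
RSP5
ART1
BUL1
EDE1
SLA1
SLA2
PAN1
END3
ENT1
ENT2
RVS161
RVS167
ABP1
LAS17
VRP1
BZZ1
INP51
PKH1
PKH2
KCC4
GIN4
HSL1
ELM1
CDC28
CLB2
SSK2
YPK1
YPK2
TOR2
AVO1
AVO2
BIT61
SIN3
RPD3
UME6
SSD1
MKK1
SLT2
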