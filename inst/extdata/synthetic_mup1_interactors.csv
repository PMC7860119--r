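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
YGR130C
YAP1801
YAP1802
APL1
APL3
APM4
APS2
CHC1
CLC1
GNP1
AGP1
BAP2
TAT1
TAT2
HIP1
CAN1
LYP1
DIP5
PUT4
FUR4
GAP1
MEP2
HXT1
SEC9
SSO1
SSO2
SNC1
SNC2
VPS27
HSE1
VPS23
SNF7
VPS4
DOA4
MYO3
MYO5
BBC1
SHO1
ARC18
ARP2
ARP3
ARC15
ARC19
ARC35
ARC40
COF1
CAP1
CAP2
SAC6
SCP1
TPM1
TPM2
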