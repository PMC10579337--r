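gene
AURKA
CCNA2
CCND1
CCNE2
CDK1
CEP63
CEP152
E2F1
E2F2
LMO4
MDM2
MYCN
NDRG1
NEK2
PIN1
PLK1
PLK4
SASS6
STIL
TUBG1
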