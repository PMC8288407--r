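GATA1
GATA2
GATA3
KLF1
TAL1
LMO2
NFE2
GFI1
GFI1B
SPI1
CEBPA
CEBPB
CEBPE
IRF4
IRF8
PAX5
EBF1
TCF3
TCF4
LEF1
TBX21
EOMES
PRDM1
XBP1
RUNX1
RUNX3
MYB
IKZF1
FLI1
ETV6
HOXA9
MEIS1
MEF2C
BCL11A
BCL11B
ID2
STAT4
STAT5A
ZBTB16
NFIL3
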