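ABCB1
BCL3
FGFR1
FGFR4
IL6
MMP9
MYCN
PTGS2
PTK7
TGFBR2
TGFBR3
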