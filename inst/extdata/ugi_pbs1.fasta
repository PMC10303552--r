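>Ugi_PBS1 uracil-DNA glycosylase inhibitor Ugi, Bacillus phages PBS1/PBS2/AR9 (YP_009664501.1)
MTNLSDIIEKETGKQLVIQESILMLPEEVEEVIGNKPESDILVHTAYDESTDENVMLLTS
DAPEYKPWALVIQDSNGENKIKML
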