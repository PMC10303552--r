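>SAUGI_like_synthetic synthetic stand-in for SAUGI (Q936H5): 112 aa, 17 acidic residues, ECESIEEI at 24-31, ESI + E-X(6)-[ED]-[ED] motifs
MEAILYKMDFWAIGYEMHFWPIDECESIEEIKEDYTMHGWEINYTPHDWSINGTEHQWSP
NDTVHQGSENLTVPQDSANLTVEQFSANLKVMQFSARLYVMQFKAILYVMRF
>Ugi2_like_synthetic synthetic stand-in for Ugi-2 (ALN97938): 87 aa, 21 acidic residues, KICHSTSL at 45-52, ESI + E-X(6)-[ED]-[ED]-X-[ED]-[ED] motifs
METSRAEIDNQKFDWESVQEAILMLTEEVEDGMEHDQLPYDTEVKICHSTSLAGIENDLF
PWDSEAMGHKQDFYPTRVEMIGNKLDY
>MCUGI1_like_synthetic synthetic stand-in for MCUGI1 (WP_101156358.1): 110 aa, 18 acidic residues, LTEFVQLG at 24-31, ESI + E-X(6)-[ED]-[ED] motifs
MEDPLQNHIMDEGAVSTWYEDPFLTEFVQLGTDELQNHIDEGMAVSTWEKPYFLQNHDRG
IMAVSTEKTWYFLQNDRNHIMAVSEKSTWYFLQDRQNHIMAVEGVSTWYF
>p56_like_synthetic synthetic stand-in for PZA p56 (NP_040721.1): 56 aa, acidic, E-X(2)-Y-X(0,2)-G match (EKSYTG at 10-15)
MEYQIVGKDEKSYTGDIVWLPREEWLHATKDDHATFNREETFNMSGDDNMSYQPEE
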