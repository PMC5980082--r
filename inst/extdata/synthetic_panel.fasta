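>REF_I-N_1
PMRESSDGVIWRKYGQKYRPMFPIVIEDFCGARNCPVVVIYSPFFMKESIFANIAFQSHP
HRGPKMV
>REF_I-N_2
PMRESSRGVIWRKYGQKYRPMFPIVIEDNCGARNCPVQVIYSPFFMKESIFANIAFQSHP
HRGPKMV
>REF_I-N_3
PMRESSRGVIWRKYGQKYRPMFPIVIEDFCGARNCPVVVIYSPFFMKESIFANIAFQSHP
HRGPNMV
>REF_I-C_1
RMRENSDGVIWRKYGQKTRPMFPIVIEDFCIARNCSVVVIYSNYNMKDNIFQNIAFMSHP
HRKPKMV
>REF_I-C_2
RMRESSAGVIWRKYGQKTRPMFPIVIEDFCIARECSVVVIYSNYNMKDNIFQNIAFMSHP
HRKPKMV
>REF_I-C_3
RMRESSDGVIWRKYGQKTRPMFPIVIEDFCIARNCSVVVIYSNYNMKDNIFQNIAFMSHP
HRKPKMA
>REF_IIa_1
DMREPFDGVAWRKYGQKYRPIFPIVTEDMCQSANMCSDVYRKRNPNPFEIINTNGAKRSH
PHQKPKEV
>REF_IIa_2
DMREPFDGVIWRKYGQKYRPIFPIFTEDMCQSANMCSDVYRKRNPNPFEGINTNGAKRSH
PHQKPKEV
>REF_IIa_3
GMREPFDGVIWRKYGQKYRPIFPIVTEDMCQSANMCSDVYRKRNPNPFEMINTNGAKRSH
PHQKPKEV
>REF_IIb_1
FMREPFRGVIWRKYGQKYRPMFPIVTEDFCQSANMCSDVYSKRNDNMFEMINTNGASNSH
FHQKPPMQ
>REF_IIb_2
FMREPFRGVIWRKYGQKYRPMFPIVTEDFCQSANMCSDVYSKRNDNMFEMIPTNGASSSH
GHQKPPMQ
>REF_IIb_3
FMREPFRGIIWRKYGQKIRPMFPIVTEDFCQSANMCSDVYSKRNDNMFEMINTNGASSSH
DHQKPVMQ
>REF_IIc_1
TMRENSRGFIWRKYGQKYRMMFGIMTEDFCASRNCSGVYIKRNKQFFGMIFTNGTKMHPH
QKIKMV
>REF_IIc_2
TMRENSRGFIWRKYGQKYRMMFGIMTEDFCASRNCSGVYIKRNKSFAGMIFTNGTKMHPH
QKIKMV
>REF_IIc_3
TMRENSRGFIWRKYGQKYQMMFGIMTEDNCASRNCSGVRIKRNKQFFGMIFTNGTKMHPH
QKIKMV
>REF_IId_1
AMRMGSRGVIWRKYGQKMRPDFQIVTEDECGSREMCSDVYIKRDKGMRDNIFTAGAKMHP
HQKPKMY
>REF_IId_2
AMRMGSRGVDWRKYGQKMRMDFQIVTEDECGSREMCSDVYIKRDKGMAENIFTQGAKMHP
HQKPKMY
>REF_IId_3
AMRMGSRGVIWRKYGQKMRPDFQIVTEDECGSREMCSDVYIKRDKGMAENIFTQGAKMHP
HQKPKMY
>REF_IIe_1
FMRMGSFGVIWRKYGQKDRPDFQIVTEDVCVSTEMCSQVMIKRIKGMNEMIFTNGSKMHP
HQDGKMY
>REF_IIe_2
FMRMGSFGVIWRKYGQKYRPDFQIVTEDECVSTEMCSQVMIKRIKGMNEMIFTNGSKMHP
HQDPKMY
>REF_IIe_3
FMRMGSFGVIWRKYGQKYRPTFQIVTEDECVSTEMCSQVMITRIKGGNEMIFTNGSKMHP
HQDPKMY
>REF_III_1
KMRPNSAGVIWRKYGQKYRPMFPIVTPDFCMDSNMTQCSDVYIKYNRNMFDGTFRNPAKM
GHPCQKPTMV
>REF_III_2
KMRPNSAGVIWRKYGQKYRPMFPIVTEDFCMDSNMTQCSDVYIKYNRNMFDGTFTNPAKM
GHPCQKPTMV
>REF_III_3
KIRPNSAGVIWRKYGQKYRPMFPIVTEDFCMDTNMTQCSDVAIKYNRNMFDGASRNPAKM
MHPCQKPTMV
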