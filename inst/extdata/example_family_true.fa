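>seq01
UCGU-GAACACCCACGCUUGCAGCGUAUGACCGAGA-CGUUGAUCCAACGA-AGAAGCAUAAU
>seq02
-CGU-GAACACCCUCGCUUGCAGCGAAUGAACUAGACACUUGUACCAAGUA-AGAAG-UUC-U
>seq03
UGGCGGAACCACCAAACCUGCGGUUUACGCCCUAACGAAUGCUACGCAUUCCUCGAGGUC--U
>seq04
UGGC-GAACCACCAAACCCGCGGUUUACCCCCCACCGCCGGCUACGCCGGC-UCGACGUCA-U
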