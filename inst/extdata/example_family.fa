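>seq01
UCGUGAACACCCACGCUUGCAGCGUAUGACCGAGACGUUGAUCCAACGAAGAAGCAUAAU
>seq02
CGUGAACACCCUCGCUUGCAGCGAAUGAACUAGACACUUGUACCAAGUAAGAAGUUCU
>seq03
UGGCGGAACCACCAAACCUGCGGUUUACGCCCUAACGAAUGCUACGCAUUCCUCGAGGUCU
>seq04
UGGCGAACCACCAAACCCGCGGUUUACCCCCCACCGCCGGCUACGCCGGCUCGACGUCAU
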