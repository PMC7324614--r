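>SYNV1
CCGAACAGTACGTCTCCGTTAGTTTCAACTTTGCCGTCCCCAAACGGCGGGGGCTACAGCCTGCTAAACTCTAGCGTTAC
CGTTAGTGGACTCCACCTACTTACTCCTGGTGCGGTTTGT
>SYNV2
AAATTCGCCCCATTCAACGCAGTCATCGTAAGAGTACAGAGTAGTGCCACAGGCTTTCTACCCCACTACTACTTAATCGG
GATAGAAATGATTGCTTTAGGATCTGTTTCGGGCGTATGT
>SYNV3
CGGGGAAGAGCGCAGCTAGACAGAGGGTTATCTGTGAAGCTAGCTTATTTCTGTCCGCCTAATAGTGGCGTGCTCGTGCA
CGGGCCAATGTGGGTGCCCATCCATATCCTTCTATTGTGT
>SYNV4
TTGGCCACGATGCACTACACCACACGGACGGCACAAAGTAGCGTGGTGAGGCGCCATAAACTGCGGTATGTGATCATTGG
CCTCAATGTCACAGAGATCCTCCATCGCTCCGCCGAGTGT
>SYNJ1
TGGGTACGGCAATTTGCCACCATCCCGACGTTGTTGTATCGACAGGAA
>SYNJ2
TGGCTCTACGGCAAACTGCCCCACTTTGTTAAGGGGTACAGGGCAGTC
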