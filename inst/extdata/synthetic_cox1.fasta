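>cox1_synthetic
CCACGTGAGGTGCATCCATTCACCATTCTCGCTGACAACTTTACTCCGCTTTTGAGGAATGCGTCAACGA
AAATAGATTATATGGTAAAAGAACCGTTGTGAATCCGGTATCGTTTATTCTTTTGTCCAGCTGCCTCAGG
AATGGCACAAGTGTGGAAAGCTTATATTAAGTTTTACTGGCCTAGGCGAAAGAAAATAGGCTCTATCTAA
TGTATCTTTCTATCTCAAAATAAACGACTTATAATTAATCTAATAGATTTGATCTACACCAGTACTTTTT
TAACTATATACGTTTAGTAATTATCCTATAACTAACAGCCTTAATCTCGGCAATGTTTCATAGTAACTGC
TTAAGTGCTTTGACGTTCTAATGAGCAAACTTTATCACAACTGAGTCCTAATGTCACAATATAGAAAGTA
ATCCTATTGTTTTACATAATGCTCATAGGATTGGTAAGCCTACAAGTATCTACCTTTCAGATCACTCAAA
CTCTTAGAAAAATCACTACAAGAATTAATTGCCAGGACTACAGGTAATTAGCTATGGATTCAGAAACACG
GAAAATGATGGACAAGAATTACGGATCCTGTCTCGTTTATTAGATTGATTTTGTCCAATTTTAGAGATGT
TAAATGATCGTATCTGTTCCACCGTTAATTGCTCAGTTCATGATAAAAATTCGCTCAAGTTACCAGTCCT
GTAGGGAATTCCTGGGTAAGAGATTCTTTTTCCCATTGGCCTTCCTAGCTAATAAATACCCGAAGGCTTT
TATAGACCGCGGTAGAAGTACTGATATACACCATTATAATACTTGTCAATAGTAACAAAAATATTTAGCA
GGATTAATCATGATGATCTCCGAATCAATTCCACTGATCTCGGGCAAACGATGTTCTAGGAATATCTATA
TTCCGGCTAAGCCATCATATTCCCGAATAGTTATGTAGTATTTGTTGGGGTGACACAAGATTTTAAATGA
TATGTACAACGACCAATATACACTTATGACTTAAACAAGACATAATTACCCAAATTCGTACTTGGATCCA
CAAGACGTAAACAATGCATGTATCAGCAAATCTGGACTGACAGTATTACTAGGATGGTGCTTCGAACGAC
GCTTCGTGATAGGATTAATTACTGAAATTACACGTCTTCATTTTAAATGTAGCCAATCTCTATAGGTTTC
TGTACGAACTTTGACCGTAGCCATGTATACAGTTCCTACTGAAGCTGTTACTGCACGGAGGGTAGAGATC
GGGATTCTCTAGATGGAGTTGTAAAGGGATAAAGGATTGTGCTAACGCCTAGATTTATGTATCCTGGCCT
TACCTGAATTGAGTTCATGTAGAAGAATTATCATCTAACATGATTATATCACAAGAATATACATATTATT
TAGTAATGATATAAATGATCTTCGTCAAGCTCCGTGACATGACTTTTCGCCTGTACAAAATGTAGGAATA
GATCATCTTGACCTATACATGAATTGTGTAACACTGTAATTAGACATATCGTTGTATGGCTCAG
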