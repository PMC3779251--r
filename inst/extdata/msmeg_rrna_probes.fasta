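>16S-1
GTAGCCGGCCTGAGAGGGTGACCGGCCACACTGGGACTGAGATACGGCCCAGACTCCTACGGGAGGCAGCAGTGGGGAATATTGCACAATGGGCGCAAGC
>16S-2
GACGCCGCGTGAGGGATGACGGCCTTCGGGTTGTAAACCTCTTTCAGCACAGACGAAGCGCAAGTGACGGTATGTGCAGAAGAAGGACCGGCCAACTACG
>16S-3
TGCCAGCAGCCGCGGTAATACGTAGGGTCCGAGCGTTGTCCGGAATTACTGGGCGTAAAGAGCTCGTAGGTGGTTTGTCGCGTTGTTCGTGAAAACTCAC
>16S-4
AGCTTAACTGTGGGCGTGCGGGCGATACGGGCAGACTAGAGTACTGCAGGGGAGACTGGAATTCCTGGTGTAGCGGTGGAATGCGCAGATATCAGGAGGA
>16S-5
GGTGGCGAAGGCGGGTCTCTGGGCAGTAACTGACGCTGAGGAGCGAAAGCGTGGGGAGCGAACAGGATTAGATACCCTGGTAGTCCACGCCGTAAACGGT
>23S-1
ATCTCAGTACCCGTAGGAAGAGAAAACAAAATGTGATTCCGTGAGTAGTGGCGAGCGAAAGCGGAGGATGGCTAAACCGTATGCATGTGATACCGGGTAG
>23S-2
GGGTTGTGTGTGCGGGGTTGTGGGACCTATCTTTCCGGCTCTACCTGGCTGGAGGGCAGTGAGAAAATGTTGTGGTTAGCGGAAATGGCTTGGGATGGCC
>23S-3
AGGCCAATCAAACTCCGTGATAGCTGGTTCTCCCCGAAATGCATTTAGGTGCAGCGTCGCATGTTTCTTGCCGGAGGTAGAGCTACTGGATGGCCGATGG
>23S-4
CGAAAGTCGGGACTAGTGATCCGGCACCTCTGAGTGGAAGGGGTGTCGCTCAACGGATAAAAGGTACCCCGGGGATAACAGGCTGATCTTCCCCAAGAGT
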