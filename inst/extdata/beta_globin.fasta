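>Human
ATGGTGCACCTGACTCCTGAGGAGAAGTCTGCCGTTACTGCCCTGTGGGGCAAGGTGAAC
GTGGATGAAGTTGGTGGTGAGGCCCTGGGCAG
>Chimpanzee
ATGGTGCACCTGACTCCTGAGGAGAAGTCTGCCGTTACTGCCCTGTGGGGCAAGGTGAAC
GTGGATGAAGTTGGTGGTGAGGCCCTGGGCAGGTTGGTATCAAGG
>Gorilla
ATGGTGCACCTGACTCCTGAGGAGAAGTCTGCCGTTACTGCCCTGTGGGGCAAGGTGAAC
GTGGATGAAGTTGGTGGTGAGGCCCTGGGCAGG
>Lemur
ATGACTTTGCTGAGTGCTGAGGAGAATGCTCATGTCACCTCTCTGTGGGGCAAGGTGGAT
GTAGAGAAAGTTGGTGGCGAGGCCTTGGGCAG
>Rat
ATGGTGCACCTAACTGATGCTGAGAAGGCTACTGTTAGTGGCCTGTGGGGAAAGGTGAAC
CCTGATAATGTTGGCGCTGAGGCCCTGGGCAG
>Mouse
ATGGTGCACCTGACTGATGCTGAGAAGTCTGCTGTCTCTTGCCTGTGGGCAAAGGTGAAC
CCCGATGAAGTTGGTGGTGAGGCCCTGGGCAGG
>Rabbit
ATGGTGCATCTGTCCAGTGAGGAGAAGTCTGCGGTCACTGCCCTGTGGGGCAAGGTGAAT
GTGGAAGAAGTTGGTGGTGAGGCCCTGGGCAG
>Goat
ATGCTGACTGCTGAGGAGAAGGCTGCCGTCACCGGCTTCTGGGGCAAGGTGAAAGTGGAT
GAAGTTGGTGCTGAGGCCCTGGGCAG
>Bovine
ATGCTGACTGCTGAGGAGAAGGCTGCCGTCACCGCCTTTTGGGGCAAGGTGAAAGTGGAT
GAAGTTGGTGGTGAGGCCCTGGGCAG
>Opossum
ATGGTGCACTTGACTTCTGAGGAGAAGAACTGCATCACTACCATCTGGTCTAAGGTGCAG
GTTGACCAGACTGGTGGTGAGGCCCTTGGCAG
>Gallus
ATGGTGCACTGGACTGCTGAGGAGAAGCAGCTCATCACCGGCCTCTGGGGCAAGGTCAAT
GTGGCCGAATGTGGGGCCGAAGCCCTGGCCAG
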