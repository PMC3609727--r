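>t1
TGTACACTCTTATTGATCGGGATACTTTAGATAGTTGCAAGGGACTCCACGTGGCTATTCCCCGGGACAC
AATGCAGACCTATATAAGCGAGTGCTGGCTCGATAATGTAGAAGCGCCATGAAACGACATTCTCACTTTT
AAGGAACGACCGACCACAGGCTCACGGGCCCGAGTCAAGGGTGATATGTCCAGGATATGAGCAATCCGTT
ATAGGTCGCATTTGGCCACGGAGTTATCAACGGTTGGTTGATCAAGTAGGGATCGGGATCCGTCGCTTGA
CGGACACATATAGAACAGGACCAGATCGCGCACTATAAGCGGAGATTAAGCGAAGCGATGAATACATCTC
GGATGGGGCGTCAACGGCATGTGCACCTTCTATGGTGCAACCATGACACCTAGGACCGTAGAGACTCCCG
GCTAAATTCCGAGGTGATGCAGGATTGCGGCCGGCAATGAATCCACTTCCCAAAAACGACCCGCACATAC
CTGATCCACGGACAGATGACGGCACTGTACGATTTAGACATAGAGAGCAGATTTTTCCTTGACGGATTTT
CGCTCTTTACACTTCGGACGATTCTAATCGTTCCTAAATG
>t2
TGTACACTCTTATTGATCGGGATACTTTAGATAGTTGCAAGGGATTCCACGTGGCTATTCCCCGGGACAC
AATGCAGACCTATATAAGCGAGTGCTGGCTCGATAATGTAGAAGCGCCATGAAACGACATTCTCACTTTT
AAGGAACGACCAACCACAGGCTCACGGGCCCGAGTCAAGGGTGATGTGTCCAGGATATGAGCAATCCGTT
ATAGGTCGCATTTGGCCACGGAGTTATCAACGGTTGGTTGTTCAAGTAGGGAACGGGATCCGTCGCTTGA
CGGACACATATAGAACTGGACCAGATCGCGCACTATAAGCGGAGATTAACCGAAGCGATGAATACATCTC
GGATGGGGCGTCAACTGCATGTGCACCTTCTATGGTGCAACCATGACACCTAGGACCGTAGAGACTCCCG
GCTAATTTCCGAGGTGATGAAGGATTGCGGCCGGCAATGAATCCACTTCCCAAAAACGACCCGCACATAC
CTGATCCACGGACAGATGACGGCACTGTACGATTTAGACATAGAGAGCAGATTTTTCCTTGACGGATTTT
CGCTGTTTACACTTCGGACGATCCTAATCGTTCCTAAATA
>t3
TGTACACTCTTATTGATCGGGAGACTTTAGATAGTTGCAAGGGACTCCACGTGGCTATTCCCCGGGACAC
AATGCAGACCTATATAAGCGACTGCTGGCTCGATAATGTAGAAGCGCCCTGAAACGACATTCTCACTGTT
AAGGAACGACCAAACACAGGCTCACGGGCCCGAGTCAAGGGTGATGTGTCCAGGATATGAGCAATCCGTT
ATAGGTCGCATTTGGCCACGGAGTTATCAACGGATGGTTGTTCAAGTAGGGAGCGGGATCCGTCGCTTGA
CGGACACATATAGAACAGGACCAGATCGCGCACTATAAGCGGAGATTAACCGAAGCGATGAATACATCTC
GGATGGGGCGTCAACTGCATGTGCACCTTCTATGGTGCAACCCTGACACCTAGGACCGTAGAGACTCCCG
GCTAAATTCCGAGGTGATGCAGGATTGCGGCCGGCAATGAATCCACTTCCCAAAAACGACCCGCACATAC
CTGATCCACGGACAGATGACGGCACTGTACGATTTAGACATAGAGAGTAGATTTTTCCATGACGGATTTT
CGTTCTTTACACTTCGGACGATCATAATCGTTCCTAAATG
>t4
TGTACTCTCTTATTGATCGGGATACTTTAGATAGTTGCAAGGGACTCCACGTGGCTATTCCACGGGACAC
AATGCAGACCTATATAAGCGACTGCTGGCTCGATAATGTAGAAGCGCCCTGAAACGACATTCTCACTGTT
AAGGAACGACCAAACACAGGCTCACGGGCCCGAGTCAAGGGTGATGTGTCCAGGATATGAGCAATCCGTT
ATAGGTCGCATTTGGCCACGGAGTTATCAACGGATGGTTGTTCAAGTAGGGAGCGGGATCCGTCGCTTGA
CGGACACATATAGAACAGGACCAGATCGCGCACTATAAGCGGAGATTAACCGAAGCGATGAATACATCTC
GGATGGGGCGTCAACTGCATGTGCACCTTCTATGGTGCAACCCTGACACCTAGGACCGTAGAGACTCCCG
GCTAAATTCCGAAGTGATGCAGGATTGCGGCCGGCAATGAATCCACTTCCCAAAAACGACCCGCACATAC
CTGATCCACGGACAGATGACGGCACTGTACGATTTTGACATAGAGAGTAGATTTTTCCATGACGGATTTT
CGCTCTTTACACTTCGGACGATCCTAATCGTTCCTAAATG
>t5
TGTACACTCTTATTGATCGGGATACTTTAGATAGTTGCAAGGGACTCCACGTGGCTATTCCCCGGGCCAC
AATGCAGACCTATATAAGCGACTGCTGGCTCGATAATGTAGAAGCGCCCTGAAACGACATTCTCACTGTT
AAGGAACGACCAAACACAGGCTCACGGGCCCGAGTCAAGGGTGATGTGTCCAGGATATGAGCAATCCGTT
ATAGGTCGCATTTGGCCACGGAGTTATCAACGGATGGTTGTTCAAGTAGGGAGCGGGATCCGTCGCTTGA
CGGACACATATAGAACAGGACCAGATCGCGCACTATAAGCGGAGATTAACCGAAGCGATGAATACATCTC
GGATGGGGCGTCAACTGCATGTGCACCTTCTATGGTGCAACCCTGACACCTAGGACCGTAGAGACTCCCG
GCTAAATTCCGAGGTGATGCAGGATTGCGGCCGGCAATGAATCCACTTCCCAAAAACGACCCGCACATAC
CTGATCCACGGACAGATGACGGCACTGTACGATTTTGACATAGAGAGTAGATTTTTCCATGACGGATTTT
CGCTCTTTACACTTCGGACGATCCTAATCGTTCCTAAATG
>t6
TGTACACTCTTATTGATCGGGATACTTTAGATAGTTGCAAGGGACTCCACGTGGCTATTCCCCGGGACAC
AATACAGACCTACATAAGCGACTGCTGGCTCGATAATGTAAAAGCGCCCTGAAACGACATTCTCACTGTT
AAGGAACGACCAAACACAGGCTCACGGGCCCGAGTCAAGGGTGATGTGTCCAGGATATGAGCAATCCGTT
ATAGGTCGCATTTGGCCACGGAGTTATCAACGGATGGTTGTTCAAGTAGGGAGCGGGATCCGTCGCTTGA
CGGACACATATAGAACAGGACCAGATCGCGCACTATAAGCGGAGATTAACCGAAGCGATGAATACATCTC
GGATGGGGCGTCAACTGCATGTGCACCTTCTATGGTGCAACCCTGACACCTAGGACCGTAGAGACTCCCG
GCTAAATTCCGAGGTGATGCAGGATTGCGGCCGGCAATGAATCCACTTCCCAAAAACGACCCGCACATAC
CTGATCCACGGACAGATGACGGCACTGTACGATTTAGACATAGAGAGTAGATTTTTCCATGACGGATTTT
CGTTCTTTACACTTCGGACGATCCTAATCGTTCCTAAATG
>t7
TGTACACTCTTATTGATCGGGATACTTTAGATAGTTGCAAGGGACTCCACGTGGCTATTCCCCGGGACAC
AATACAGACCTACATAAGCGACTGCTGGCTCGATAATGTAAAAGCGCCCTGAAACGACATTCTCACTGTT
AAGGAACGACCAAACACAGGCTCACGGGCCCGAGTCAAGGGTGATGTGTCCAGGATATGAGCAATCCGTT
ATAGGTCGCATTTGGCCACGGAGTTATCAACGGATGGTTGTTCAAGTAGGGAGCGGGATCCGTCGCTTGA
CGGACACATATAGAACAGGACCAGATCGCGCACTATAAGCGGAGATTAACCGAAGCGATGAATACATCTC
GGATGGGGCGTCAACTGCATGTGCACCTTCTATGGTGCAACCCTGACACCTAGGACCGTAGAGACTCCCG
GCTAAATTCCGAGGTGATGCAGGATTGCGGCCGGCAATGAATCCACTTCCCAAAAACGACCCGCACATAC
CTGATCCACGGACAGATGACGGCACTGTACGATTTAGACATAGAGAGTAGATTTTTCCATGACGGATTTT
CGTTCTTTACACTTCGGACGATCCTAATCGTTCCTAAATG
>t8
TGTACACTCTTATTGATCGGGTTACTTTAGATAGTTGCAAGGGATTCCACGTGGCTATTCCCCGGGACAC
AATGCAGACCTATATAAGCGAGTGCTGGCTCGATAATGTAGAAGCGCCATGAAACGACATTCTCACTTTT
AAGGAACGACCAACCACAGGCTCACGGGCCCGAGTCAAGGGTGCTGTGTCCAGGATATGAGCAATCCGTT
ATAGGTCGCATTTGGCCACGGAGTTATCTACGGTTGGTTGTTCAAGTAGGGAACGGGATCCGTCGCTTGA
CGGACACATATAGAACTGGACCAGATCGCGCACTATAAGCGGAGATTAACCGAAGCGATGAATACATCTC
GGATGGGGCGTCAACTGCATGTGCACCTTCTATGGTGCAACCATGACACCTAGGACCGTAGAGACTCCCG
GCTAATTTCCGAGGTGATGCAGGATTGCGGCCGGCAATGAATCCACTTCCCAAAAACGACCCGCACATAC
CTGATCCACGGACAGATGACGGCACTGTACGATTTAGACATAGAGCGCAGATTTTTCCTTGACGGATTTT
CGCTCTTTACACTTCGGACGATCCTAATCGTTCCTAAATA
>t9
TGTACACTCTTATTGATCGGGTTACTTTAGATAGTTGCAAGGGATTCCACGTGGCTATTCCCCGGGACAC
AATGCAGACCTATATAAGCGAGTGCTGGCTCGATAATGTAGAAGCGCCATGAAACGACATTCTCACTTTT
AAGGAACGACCAACCACAGGCTCACGGGCCCGAGTCAAGGGTGCTGTGTCCAGGATATGAGCAATCCGTT
ATAGGTCGCATTTGGCCACGGAGTTATCTACGGTTGGTTGTTCAAGTAGGGAACGGGATCCGTCGCTTGA
CGGACACATATAGAACTGGACCAGATCGCGCACTATAAGCGGAGATTAACCGAAGCGATGAATACATCTC
GGATGGGGCGTCAACTGCATGTGCACCTTCTATGGTGCAACCATGACACCTAGGACCGTAGAGACTCCCG
GCTAATTTCCGAGGTGATGCAGGATTGCGGCCGGCAATGAATCCACTTCCCAAAAACGACCCGCACATAC
CTGATCCACGGACAGATGACGGCACTGTACGATTTAGACATAGAGAGCAGATTTTTCCTTGACGGATTTT
CGCTCTTTACACTTCGGACGATCCTAATCGTTCCTAAATA
>t10
TGTAAACTCTTATTGTTCGGGATACTTTAGATAGTTGCAAGGGATTCCACGTGGCTATTCCCCGGGACAC
AATGCAGACCTATATAAGCGAGTGCTGGCTCGATAATGTAGAAGCGCCATGAAACGACATTCTCACTCTT
AAGGAACGACCAACCACAGGCTCACGGGCCCGAGTCAAGGGTGATGTGTCCAGGATATGAGCAATCCGTT
ATAGGTCGCATTTGGCCACGGAGTTATCAACGGTTGGTTGTTCAAGTAGGGAACGGGATCCGTCGCTTGA
CGGACACATATAGAACTGGACCAGATCGCGCACTATAAGCGGAGATTAACCGAAGCGATGAATACATCTC
GGATGGGGCGTCAACTGCATGTGCACCTTCTATGGTGCAACCATGACACCTAGGACCGTAGAGACTCCCG
GCTAATTTCCGAGGTGATGCAGGGTTGCGGCCGGCAATGAATCCACTTCCCAAAAACGACCCGCACATAC
CTGATCCACGGACAGATGACGGCACTGTACGATTTAGACATAGAGAGCAGATTTTTCCTTGACGGATTTT
CGCTCTTTACACTTCGGACGATCCTAATCGTTCCTAAATA
>t11
TGTAAACTCTTATTGTTCGGGATACTTTAGATAGTTGCAAGGGATTCCACGTGGCTATTCCCCGGGACAC
AATGCAGACCTATATAAGCGAGTGCTGGCTCGATAATGTAGAAGCGCCATGAAACGACATTCTCACTCTT
AAGGAACGACCAACCACAGGCTCACGGGCCCGAGTCAAGGGTGATGTGTCCAGGATATGAGCAATCCGTT
ATAGGTCGCATTTGGCCACGGAGTTATCAACGGTTGGTTGTTCAAGTAGGGAACGGGATCCGTCGCTTGA
CGGACACATATAGAACTGGACCAGATCGCGCACTATAAGCGGAGATTAACCGAAGCGATGAATACATCTC
GGATGGGGCGTCAACTGCATGTGCACCTTCTATGGTGCAACCATGACACCTAGGACCGTAGAGACTCCCG
GCTAATTTCCGAGGTGATGCAGGGTTGCGGCCGGCAATGAATCCACTTCCCAAAAACGACCCGCACATAC
CTGATCCACGGACAGATGACGGCACTGTACGATTTAGACATAGAGAGCAGATTTTTCCTTGACGGATTTT
CGCTCTTTACACTTCGGACGATCCTAATCGTTCCTAAATA
>t12
TGTAAACTCTTATTGTTCGGGATACTTTAGATAGTTGCAAGGGATTCCACGTGGCTATTCCCCGGGACAC
AATGCAGACCTATATAAGCGAGTGCTGGCTCGATAATGTAGAAGCGCCATGAAACGACATTCTCACTCTT
AAGGAACGACCAACCACAGGCTCACGGGCCCGAGTCAAGGGTGATGTGTCCAGGATATGAGCAATCCGTT
ATAGGTCGCATTTGGCCACGGAGTTATCAACGGTTGGTTGTTCAAGTAGGGAACGGGATCCGTCGCTTGA
CGGACACATATAGAACTGGACCAGATCGCGCACTATAAGCGGAGATTAACCGAAGCGATGAATACATCTC
GGATGGGGCGTCAACTGCATGTGCACCTTCTATGGTGCAACCATGACACCTAGGACCGTAGAGACTCCCG
GCTAATTTCCGAGGTGATGCAGGGTTGCGGCCGGCAATGAATCCACTTCCCAAAAACGACCCGCACATAC
CTGATCCACGGACAGATGACGGCACTGTACGATTTAGACATAGAGAGCAGATTTTTCCTTGACGGATTTT
CGCTCTTTACACTTCGGACGATCCTAATCGTTCCTAAATA
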