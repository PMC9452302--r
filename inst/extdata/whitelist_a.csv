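index,sequence
1,CAAGTGAC
2,ACGATATT
3,TACGTAAG
4,TAACCCCC
5,TTAGCTTA
6,CCCCATCC
7,CAAAATTT
8,GGACAGGA
9,ACCTGAGG
10,TGCACTTT
11,GGAAGGAC
12,TCAAACGG
13,ACAGATGA
14,GCGCCTTA
15,GCCGGGCA
16,TCCCACTA
17,TATCGCTC
18,CGTGTATA
19,TCGAGTCA
20,TTCGTTGG
21,ACTACGCA
22,TCTCCATG
23,CGGCAAGA
24,TAGCGCAA
25,GGTGAGAC
26,TTGTGCGC
27,GTGCATGA
28,TTTGCTAG
29,CTGCCCCT
30,TATCAGAA
31,TTCACGCG
32,CTCCTGCC
33,ATTGAGAG
34,TTCCCAGG
35,CAGCCTAC
36,GTACAGAG
37,ATGAGACC
38,ACGCACCG
39,GCATAAGC
40,CCCCTATA
41,GTCAATAG
42,TCCGTGTG
43,CAAGAGGG
44,AGAGTTAA
45,CAGATTCG
46,TAGTCGGA
47,ATGTGGAC
48,GCAGGACT
49,CGAGGGAG
50,GGCAATCC
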