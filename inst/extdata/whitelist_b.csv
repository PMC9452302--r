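index,sequence
1,CGCACCCG
2,GTGGGTTA
3,GAAGAGCC
4,TACGGTAT
5,TGAGTAGG
6,CGGACAAG
7,GGAGTGGA
8,GAATCAAC
9,CGCGCTTT
10,GGATACGG
11,CCTGATTG
12,GCCAAGCT
13,AAGACCGC
14,AAGGTATC
15,AAAGTGAG
16,ACTTTCCA
17,CAACTACA
18,CCTAGATC
19,TGTAACTA
20,TACTACAT
21,GTGACCTG
22,GCCCATAT
23,AACCGCAA
24,CTTTGAAG
25,GTGTAAAA
26,TTTGACGC
27,CATAAAGC
28,GAGGTTCT
29,GTATCGAA
30,AGAGCTAC
31,ACTTATTT
32,TCCTCTGT
33,AATGACCA
34,TACTTGAG
35,ATGCATTC
36,GCCTTATA
37,GTAAAACT
38,TTAGCGGT
39,GATCTCTA
40,GAGAATCA
41,AGTTAATC
42,GCTCGAAG
43,TACACTGG
44,CTACAGCG
45,CACAGGAA
46,GGGTGTGA
47,CACGAAGA
48,TGTGTCTC
49,CGGCGATC
50,CCAAGCAC
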