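# SYNTHETIC stand-in pKa table for the 14 lysines of the E. meliloti L3.8
# laccase model. Only three values are published: Lys 559 = 8.92 (the one
# residue with a noticeably lowered pKa), and the extremes of the remaining
# range, Lys 565 = 10.05 and Lys 476 = 11.44. The other residue numbers and
# pKa values are synthetic placeholders spread uniformly inside the
# published 10.05-11.44 range (the per-residue appendix is not reproduced).
chain	resnum	resname	pka
A	20	LYS	10.20
A	34	LYS	10.35
A	101	LYS	10.48
A	152	LYS	10.61
A	218	LYS	10.74
A	260	LYS	10.87
A	312	LYS	11.00
A	388	LYS	11.13
A	421	LYS	11.26
A	476	LYS	11.44
A	488	LYS	10.55
A	529	LYS	10.90
A	559	LYS	8.92
A	565	LYS	10.05
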