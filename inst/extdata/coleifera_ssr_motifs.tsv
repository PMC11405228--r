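motif	repeat_count	n
A	8	33
A	9	30
A	10	4
A	11	2
A	12	2
A	13	1
C	8	5
C	9	3
G	8	14
G	9	1
T	8	41
T	9	26
T	10	8
T	11	2
T	12	2
T	15	1
T	16	1
AC	4	5
AG	4	41
AG	5	9
AG	6	1
AG	7	2
AT	4	13
AT	5	4
AT	6	3
AT	7	3
AT	8	1
AT	9	1
CA	4	1
CG	4	3
CT	4	32
CT	5	11
CT	6	2
GA	4	23
GA	5	9
GA	6	1
GC	4	2
GT	4	5
GT	5	1
TA	4	17
TA	5	6
TA	6	2
TA	7	1
TC	4	26
TC	5	3
TC	6	2
TG	4	7
AAC	4	1
AAG	4	1
AGC	4	1
GCT	4	1
TAT	4	1
TTG	4	1
ACT	4	2
CTT	4	2
GAA	4	2
TTC	4	2
TAA	4	3
TTA	4	3
TCT	4	4
GAT	5	1
AACA	3	1
AACC	3	1
AAGC	3	1
AAGG	3	1
AATA	3	1
AATG	3	1
ACTA	3	1
AGCT	3	1
AGTC	3	1
ATAA	3	1
ATGG	3	1
CAAT	3	1
CAGA	3	1
CCAG	3	1
CCGA	3	1
CCTT	3	1
CGGG	3	1
CTAG	3	1
CTCC	3	1
GAAG	3	1
GAGC	3	1
GCTT	3	1
GGCC	3	1
GTGA	3	1
TAGA	3	1
TAGT	3	1
TGAA	3	1
TTAC	3	1
TTAT	3	1
TTCC	3	1
TTTG	3	1
AAAT	3	2
ATAG	3	2
ATTC	3	2
CAAA	3	2
CTTC	3	2
CTTG	3	2
GAAA	3	2
GAAT	3	2
GATT	3	2
GGAA	3	2
AAGA	3	3
AAAG	3	4
AGAA	3	4
TCTT	3	4
TTCT	3	5
CTTT	3	6
CCTT	4	1
TATC	4	1
AATTA	3	1
ACTAG	3	1
ATAGG	3	1
CTAAT	3	1
GAAAT	3	1
GCCTT	3	1
TAAAG	3	1
TTAAT	3	1
TTATA	3	1
TAGAG	3	2
CTATCC	3	1
TTTCTA	3	1
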