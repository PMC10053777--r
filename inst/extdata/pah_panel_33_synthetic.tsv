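abbreviation	name
NAP	naphthalene
1MNAP	1-methylnaphthalene
2MNAP	2-methylnaphthalene
12DMN	1,2-dimethylnaphthalene
16DMN	1,6-dimethylnaphthalene
26DMN	2,6-dimethylnaphthalene
ACY	acenaphthylene
ACE	acenaphthene
FLO	fluorene
DBT	dibenzothiophene
PHE	phenanthrene
ANT	anthracene
2MPHE	2-methylphenanthrene
1MPHE	1-methylphenanthrene
36DMP	3,6-dimethylphenanthrene
2MANT	2-methylanthracene
9MANT	9-methylanthracene
FLA	fluoranthene
PYR	pyrene
1MPYR	1-methylpyrene
RET	retene
BAA	benz[a]anthracene
CHR	chrysene
5MCHR	5-methylchrysene
6MCHR	6-methylchrysene
BBF	benzo[b]fluoranthene
BKF	benzo[k]fluoranthene
BEP	benzo[e]pyrene
BAP	benzo[a]pyrene
PER	perylene
IcdP	indeno[1,2,3-cd]pyrene
DahA	dibenz[a,h]anthracene
BghiP	benzo[ghi]perylene
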