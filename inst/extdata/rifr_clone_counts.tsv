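# Substitution calls from sequenced rpoB amplicons of rifampicin-resistant
# colonies, as printed in the source study's report (vector arm: 32 calls;
# treated/EXOSC1 arm: 36 calls). Two tallies are recorded separately because
# the printed collapsed and stranded figures do not reconcile exactly and
# are reported here verbatim rather than harmonized:
#   channel=csub      complementary-collapsed classes: vector C>A/G>T 2/32
#                     (6%), treated C>A/G>T 25/36 (69%)
#   channel=stranded  gene-strand-resolved types: vector C>A 0/32 (0%),
#                     G>T 2/32 (6%); treated C>A 25/36 (69%), G>T 6/36 (17%)
# Classes not itemized in the report are pooled into the "rest" (csub:
# C>T/G>A, the stated dominant control class) so each arm sums to its
# printed total; only focal-vs-rest margins are used in downstream checks.
arm	channel	class	count
vector	csub	C>A/G>T	2
vector	csub	C>T/G>A	30
treated	csub	C>A/G>T	25
treated	csub	C>T/G>A	11
vector	stranded	C>A	0
vector	stranded	G>T	2
vector	stranded	rest	30
treated	stranded	C>A	25
treated	stranded	G>T	6
treated	stranded	rest	5
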