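# australia_2017 — haplogroup definition tree for Aboriginal Australian mtDNA
# lineages, rCRS-relative profile space.
#
# Format: label <TAB> parent (or "-" for root) <TAB> space-separated variant
# tokens (may be empty => topology-only placeholder node).
#
# Provenance of branch motifs:
#   [published] — diagnostic positions printed in the study's main text or
#                 standard PhyloTree Build 17 definers (M coding-region trio).
#   [synthetic] — stand-in tokens at otherwise unused positions; the true
#                 diagnostic motifs live in supplementary tables that are not
#                 distributed with this package. Do NOT interpret these
#                 positions biologically.
#   [placeholder] — named node with no motif; represents topology only and is
#                 never a classification candidate.
#
ROOT	-
M	ROOT	C10400T T14783C G15043A	# [published] PhyloTree M definers
M42	M	A9156G	# [published] defining mutation of M42
M42a	M42	G12771A G8251A	# [published] 12771 defining; 8251 hotspot shared with M42b
M42a1	M42a		# [placeholder]
M42c	M42	C64T T195C	# [published] M42c definers; note absence of G8251A
M42c1	M42c		# [placeholder]
M42c2	M42c		# [placeholder]
M42b	M42	G8251A	# [published] hotspot 8251 (26 hits in PhyloTree B17); South Asian sister
M15	M	C16193T A5363G T6620C	# [published 16193] + [synthetic 5363 6620]
M16	M	C16193T	# [published] tentative definer, shared with M15 (possibly by state)
Q	M	A4871G G5460A	# [synthetic]
Q1	Q	T7389C	# [synthetic]
N	ROOT	G1598A A2758G	# [synthetic]
S	N	A5186G	# [synthetic]; root of S is one mutation step from N
S1	S	C9253T	# [synthetic]
S2	S	G11150A	# [synthetic]
N13	N	G6257A T9824C	# [synthetic]
O	N	A5843G C12879T	# [synthetic]
R	N	T2352C C3970T	# [synthetic]
P	R	A6671G T8621C	# [synthetic]
P3	P	G9545A	# [synthetic]
P4	P	T10586C	# [synthetic]; New Guinean (former P4a)
P5	P	C4011T A13105G	# [synthetic]
P6	P	G7805A	# [synthetic]
P8	P	T12609C	# [synthetic]
P11	P	C11288T	# [published] the mutation joining former P4b with the Tasmanian P lineage
P11a	P11	A14927G	# [synthetic]; mainland
P11b	P11	G15930A	# [synthetic]; Tasmanian
P12	P	C5111T G13590A	# [synthetic]
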