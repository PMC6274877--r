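name	pattern	annotation
AE-box	AGAAACAA	Light responsive element
ARE	AAACCA	regulatory element essential for the anaerobic induction
As	TGACG	unknown
CAAT-box	CCAAT	cis-acting element in promoter and enhancer regions
CGTCA-motif	CGTCA	MeJA-responsiveness
CTAG-motif	ACTAGCAGAA	unknown
GA-motif	ATAGATAA	Light responsive element
GATA-motif	AAGATAAGATT	Light responsive element
GT1-motif	GGTTAA	Light responsive element
MBSI	AAAAAACSGTTA	MYB binding site involved in flavonoid biosynthesis
MYB	TAACYR	unknown
MYC	TCTCTTA/CAATTG	unknown
STRE	AGGGG	unknown
TATA-box	TATWWAAW	unknown
TGACG-motif	TGACG	MeJA-responsiveness
TGA-element	AACGAC	auxin-responsive element
WUN-motif	AAATTTCCT	wound-responsive element
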