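# Curated default cis-regulatory element table (IUPAC consensus strings).
# This table is replaceable data: counts are always relative to the table
# supplied, and these consensi are working definitions for the named
# elements, not the internal matrices of any external prediction server.
motif_id	consensus	stimulus
ABRE	ACGTG	Abscisic acid
CGTCA-motif	CGTCA	MeJA
AuxRR-core	GGTCCAT	Auxin
TGA-element	AACGAC	Auxin
GARE-motif	TCTGTTG	Gibberellin
P-box	CCTTTTG	Gibberellin
TATC-box	TATCCCA	Gibberellin
TCA-element	CAGAAAAGGA	Salicylic acid
SARE	TTCGACCATCTT	Salicylic acid
DRE	RCCGAC	Drought
MBS	CAACTG	Drought
LTR	CCGAAA	Low-temperature
TC-rich_repeats	ATTCTCTAAC	Defense and stress
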