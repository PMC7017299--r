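# Synthetic signed regulatory model over the eight B-cell fate regulators.
# This is a constructed stand-in edge list (18 edges) for format and
# workflow demonstrations; it is NOT a curated biological network.
RELA	PRDM1	+
RELA	IRF4	+
BACH2	AICDA	-
REL	BCL6	+
REL	AICDA	+
BACH2	PRDM1	-
BACH2	BCL6	+
BCL6	PRDM1	-
BCL6	IRF4	-
PRDM1	BCL6	-
PRDM1	PAX5	-
PRDM1	AICDA	-
PAX5	AICDA	+
PAX5	PRDM1	-
PAX5	BCL6	+
IRF4	PRDM1	+
IRF4	BCL6	-
IRF4	AICDA	-
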