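# GRAS motif catalog: name <TAB> region <TAB> pattern
# Pattern language: amino-acid letters; X or + = any residue; [ABC] = alternative set.
# The five core GRAS-domain motifs appear in canonical order LHRI, VHIID, LHRII,
# PFYRE, SAW. Literal units quoted in the primary literature (DELLA, TVHYNP,
# LXXLL, [LIVF]RITG, RVER, LX6LX6L and the XIV/XV/XVI consensus strings) are
# encoded verbatim; the remaining core-unit consensus strings are synthetic
# placeholders standing in for curated subfamily alignments.
name	region	pattern
LHRI	GRAS_domain	LR++LLX+LA++L
VHIID	GRAS_domain	VH[IV]ID
VHIID-C	GRAS_domain	[LIVF]RITG
LHRII	GRAS_domain	L++++++L++++++L++LL
LXXLL	GRAS_domain	LXXLL
PFYRE	GRAS_domain	P++FY++RE
SAW	GRAS_domain	W+G++L+W++S+W
RVER	GRAS_domain	RVER
DELLA	N_terminal	DELLA
TVHYNP	N_terminal	TVHYNP
XIV	N_terminal	TSVLDTRRSPSPPTSTSTSTL+SS++GGG
XV	N_terminal	++EQS+L+WI+GDV+DPS+G
XVI	N_terminal	RELE+ALLGPDDDD
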