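gene_symbol	is_cancer_predisposition	function_categories	terms
TLR2	0	pathogen_recognition,innate_immunity	helicobacter pylori;pathogen recognition
APC	1	tumor_suppression,gc_development	wnt signaling;gastric cancer
FAT4	1	cell_adhesion,tumor_suppression	cell adhesion;hippo signaling
CTNND1	0	cell_adhesion	cell adhesion;e-cadherin
ERCC2	1	dna_repair	dna repair;nucleotide excision repair
MUC1	0	gut_epithelial_protection	gut epithelial protection;mucin
ADH1B	0	alcohol_metabolism	alcohol metabolism
ZZZ1	0		axon guidance
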