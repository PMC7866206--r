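signature	aetiology
SBS1	clock_like
SBS5	clock_like
SBS15	mmr_deficiency
SBS19	unknown
SBS21	mmr_deficiency
ID1	clock_like
ID2	clock_like
ID7	mmr_deficiency
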