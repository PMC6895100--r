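code	parent_base	formula_delta	mono_mass_delta	blocks_watson_crick	blocks_t1_cleavage
acp3U	U	C4H7NO2	101.04768	TRUE	FALSE
D	U	H2	2.01565	FALSE	FALSE
acp3D	U	C4H9NO2	103.06333	TRUE	FALSE
psi	U		0.00000	FALSE	FALSE
m5U	U	CH2	14.01565	FALSE	FALSE
m7G	G	CH2	14.01565	FALSE	FALSE
Gm	G	CH2	14.01565	FALSE	TRUE
m1A	A	CH2	14.01565	TRUE	FALSE
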