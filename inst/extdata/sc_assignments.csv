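shift_ppm,moiety,component_class,multiplicity,source,notes
14.6,omega CH3,lipid_chain,3,main_text,terminal methyl of the hydrocarbon chains
23.3,(omega-1) CH2,lipid_chain,2,main_text,penultimate methylene
30.5,(CH2)n trans/gauche,lipid_chain,2,main_text,main-chain methylenes with liquid-like trans/gauche distribution
32.7,(omega-2) CH2,lipid_chain,2,main_text,
33.4,(CH2)n all-trans,lipid_chain,2,main_text,crystalline all-trans chain methylenes
40.6,Leu C_beta / Lys C_epsilon,keratin_core,2,main_text,compound peak; residues enriched in the coiled-coil core
40.65,cholesterol C24/C12,cholesterol,2,main_text,printed as 40.4-40.9 ppm; overlaps the keratin-core 40.6 ppm peak
42.8,cholesterol C4,cholesterol,2,main_text,
43.7,Gly C_alpha,keratin_terminal,2,main_text,referencing anchor (alpha-glycine methylene)
51.8,cholesterol C9,cholesterol,1,main_text,
56.7,Ser C_alpha,keratin_terminal,1,main_text,
57.0,keratin C_alpha region,keratin_core,1,main_text,broad backbone C_alpha envelope centred near 57 ppm
57.6,cholesterol C14/C17,cholesterol,1,main_text,
62.4,Ser C_beta,keratin_terminal,2,main_text,
172.8,carbonyl C=O,mixed,NA,fig2_caption,amide/ester carbonyl region used to scale spectra
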