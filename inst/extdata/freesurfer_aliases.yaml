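# Alias map from FreeSurfer asegstats2table column spellings to catalog ROI
# names. Matching is case-insensitive and '-', '.', and spaces are treated as
# '_' before lookup, with 'Left-'/'Right-' prefixes folded to 'L_'/'R_', so
# only spellings that differ beyond punctuation need an entry here.
Left-Accumbens-area: L_Accumbens
Right-Accumbens-area: R_Accumbens
Left-Caudate: L_Caudate
Right-Caudate: R_Caudate
Left-Putamen: L_Putamen
Right-Putamen: R_Putamen
Left-Pallidum: L_Pallidum
Right-Pallidum: R_Pallidum
Left-Anterior-amygdaloid-area-AAA: L_Anterior_amygdaloid_area
Right-Anterior-amygdaloid-area-AAA: R_Anterior_amygdaloid_area
Left-Corticoamygdaloid-transitio: L_Corticoamygdaloid_transition
Right-Corticoamygdaloid-transitio: R_Corticoamygdaloid_transition
Left-GC-ML-DG: L_GC_ML_DG
Right-GC-ML-DG: R_GC_ML_DG
Left-molecular_layer_HP: L_Molecular_layer_HP
Right-molecular_layer_HP: R_Molecular_layer_HP
Left-MV(Re): L_MV_Re
Right-MV(Re): R_MV_Re
Left-L-Sg: L_L_Sg
Right-L-Sg: R_L_Sg
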