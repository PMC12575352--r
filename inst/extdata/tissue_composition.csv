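# Fractional tissue composition for the Rodgers-Rowland partition predictor.
# f_ew/f_iw: extracellular/intracellular water (v/v); f_nl/f_np: neutral
# lipid/neutral phospholipid (v/v); ap_mg_g: acidic phospholipid (mg/g);
# pr_ratio: tissue-to-plasma albumin-equivalent binding-protein ratio.
# Rat compendium values (Rodgers & Rowland tier), applied to both species;
# reproductive_organs uses testes, red_marrow bone, yellow_marrow adipose
# (yellow marrow is fat), rest_of_body a muscle-weighted average.
tissue,f_ew,f_iw,f_nl,f_np,ap_mg_g,pr_ratio
lung,0.336,0.446,0.022,0.0128,3.91,0.212
adipose,0.135,0.017,0.853,0.0016,0.40,0.049
muscle,0.118,0.630,0.010,0.0072,1.53,0.064
liver,0.161,0.573,0.014,0.0240,4.56,0.086
spleen,0.207,0.579,0.0077,0.0113,3.18,0.097
heart,0.320,0.456,0.014,0.0111,2.25,0.157
brain,0.162,0.620,0.039,0.0015,0.40,0.033
kidney,0.273,0.483,0.012,0.0242,5.03,0.130
skin,0.382,0.291,0.060,0.0044,1.32,0.277
reproductive_organs,0.141,0.611,0.016,0.0060,2.84,0.074
red_marrow,0.100,0.346,0.017,0.0017,0.67,0.100
yellow_marrow,0.135,0.017,0.853,0.0016,0.40,0.049
rest_of_body,0.200,0.500,0.040,0.0080,2.00,0.100
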