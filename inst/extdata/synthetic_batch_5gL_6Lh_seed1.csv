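# synthetic batch observations (model-generated, not measured)
# scenario: 5 g/L glucose, 6 L/h N2 stripping, mu_max 0.20/h, seed 1
time_h,glucose_mol_L,acetate_mol_L,lactate_mol_L,biomass_molcell_L,cum_h2_mol_per_L,h2_gas_frac,co2_gas_frac
2,0.026844686308825,8.93162549299891e-05,5.24268898554553e-07,0.000136569989887918,0.000212983106112626,0.000588508259578284,0.000195370416073151
4,0.0278742838065575,0.000217765573514109,1.19124229381478e-06,0.000211209868374594,0.000497232955343322,0.000825556331418526,0.000317959738674267
6,0.0263819594200778,0.000421579346605205,2.26495805438086e-06,0.000311706143565936,0.000947023313884328,0.00119939891182265,0.000462302159599055
8,0.0296141244765808,0.0006942585229886,3.69915798751455e-06,0.000420441941929539,0.0015453453316034,0.00172243438126968,0.000655635268561354
10,0.0275632629642844,0.00107657944879054,5.48996656567595e-06,0.000646387851785693,0.00237427274789701,0.00241782402200105,0.000965021830620823
12,0.0257049803525392,0.00166245907333781,8.88895161774833e-06,0.000896037988049218,0.00371521609912348,0.00346095766649342,0.00133914471661242
14,0.0269531784857762,0.00245930281247945,1.35517342463573e-05,0.00119666496930932,0.00521760268188,0.00500860416549264,0.00181126722545162
16,0.0265863882795395,0.00348977179516529,2.09142282467651e-05,0.00183214988288449,0.00846648399857971,0.00742634103669082,0.00263844663147719
18,0.0253696393899835,0.00458529189423784,3.3789442461068e-05,0.00236565717112968,0.0118626179296389,0.00973081380652605,0.0036796291977665
20,0.0229106976501963,0.00755635965309047,5.13159106091204e-05,0.00404350098012172,0.0182381726514132,0.0146593009228409,0.00532792029517597
24,0.0199841657604456,0.0149809085804502,0.000127110215430569,0.00849773893419843,0.0355789807442957,0.0280495993154073,0.0103035661775305
28,0.0100113758268154,0.0287850675499636,0.000407548520474975,0.0139778745025696,0.0665079001561277,0.046413900866174,0.0175443746568142
32,0,0.0411321454272425,0.00113883470728577,0.0205410435598299,0.107531623484276,5.72508353778432e-05,0.00617493582432266
36,0,0.0432237054723531,0.00113087867905783,0.0217422372393484,0.102664271120943,0,0.000615510591186238
40,0,0.0452031013441857,0.00106264687197177,0.0195697080609675,0.101685045148393,0,5.89513017210251e-05
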