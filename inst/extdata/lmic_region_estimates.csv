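region,pop_3_4_millions,prevalence,prev_lower,prev_upper
East Asia/Pacific,58.5,0.259,0.125,0.393
Latin America/Caribbean,21.9,0.187,0.059,0.321
North Africa/Middle East/Central Asia,24.5,0.184,0.063,0.318
South Asia,73.4,0.377,0.243,0.511
Sub-Saharan Africa,67.0,0.438,0.305,0.572
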