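scenario,prob_source,mort_source,fb,fo,burned_area_kha,biomass_burn_area_mmt,combusted_biomass_mmt,co2_mmt,consistent
AVG_low,AVG,AVG,0.05,0.50,775.18,55.43,2.04,3.73,TRUE
AVG_med,AVG,AVG,0.30,0.80,775.18,55.43,5.37,9.84,TRUE
AVG_high,AVG,AVG,0.46,0.92,775.18,55.43,7.28,13.35,TRUE
AVG_cats,AVG,AVG,0.80,1.00,775.18,55.43,10.79,19.79,TRUE
ECP_low,ECP,model,0.05,0.50,964.61,77.44,2.53,4.63,TRUE
ECP_med,ECP,model,0.30,0.80,964.61,77.44,7.13,13.07,TRUE
ECP_high,ECP,model,0.46,0.92,964.61,77.44,9.81,17.99,TRUE
ECP_cats,ECP,model,0.80,1.00,964.61,77.44,4.88,27.28,FALSE
PLT_low,PLT,model,0.05,0.50,1426.11,115.61,3.33,6.10,TRUE
PLT_med,PLT,model,0.30,0.80,1426.11,115.61,9.08,16.65,TRUE
PLT_high,PLT,model,0.46,0.92,1426.11,115.61,12.41,22.75,TRUE
PLT_cats,PLT,model,0.80,1.00,1426.11,115.61,18.61,34.13,FALSE
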