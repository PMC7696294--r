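diet,nrd93,tc_eur_day,ghg_kgco2e_day,x_nutr,x_env,x_ec
CC,498,4.32,4.52,0.611,1.000,0.947
NDG,679,3.77,3.93,0.754,0.869,0.827
MED,662,4.51,4.07,0.736,0.903,1.000
OLV,637,2.83,2.91,0.708,0.644,0.621
VEG,632,2.36,1.41,0.702,0.312,0.518
PLH,680,3.56,2.95,0.756,0.653,0.781
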