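scenario,diet,price_eur_day,nrd93,ghg_kgco2e_day,ris,ns,c_ghg
optimized,VEG-Opt,4.28,748,1.81,0.85,1.10,1.92
optimized,PLH-Opt,2.57,717,2.12,0.91,1.06,2.21
optimized,OLV-Opt,2.88,690,2.18,0.90,1.01,2.38
optimized,NDG-Opt,2.92,728,2.61,0.90,1.07,2.71
optimized,MED-Opt,3.17,684,2.71,0.89,1.01,3.02
optimized,CC-Opt,3.33,620,3.15,0.89,0.91,3.90
predefined,VEG,2.36,632,1.41,0.92,0.93,1.65
predefined,PLH,3.56,680,2.95,0.88,1.00,3.36
predefined,OLV,2.83,637,2.91,0.90,0.94,3.44
predefined,NDG,3.77,679,3.93,0.87,1.00,4.51
predefined,MED,4.51,663,4.07,0.85,0.97,4.94
predefined,CC,4.32,498,4.52,0.85,0.73,7.28
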