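fish_id,trial,cycle_index,t_mid_s,slope,r2,mo2_abs,mo2_mass_specific
f001,initial,1,285,-2.10,0.998,0.2058,102.9
f001,initial,2,705,-2.05,0.991,0.2009,100.4
f001,initial,3,1125,-2.20,0.942,0.2156,107.8
f001,initial,4,1545,-1.98,0.987,0.1940,97.0
f001,initial,5,1965,-2.02,0.950,0.1980,99.0
f001,initial,6,2385,-2.14,0.996,0.2097,104.9
f001,initial,7,2805,-2.08,0.979,0.2038,101.9
f001,initial,8,3225,-2.11,0.899,0.2068,103.4
f001,initial,9,3645,-2.03,0.984,0.1989,99.5
f001,initial,10,4065,-2.06,0.972,0.2019,100.9
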