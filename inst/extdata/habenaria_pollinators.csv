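array,pollinator,n_bouts,n_inter_bouts,ci_mean,ci_sd
lim_dav,Deilephila elpenor,7,2,0.70,0.69
lim_dav,Trichoplusia intermixta,4,0,1.00,0.00
lim_del,Deilephila elpenor,3,0,1.00,0.00
lim_del,Trichoplusia intermixta,6,2,0.86,0.20
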