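array,pollinator,from,to,count
lim_dav,Deilephila elpenor,lim,lim,2
lim_dav,Deilephila elpenor,dav,dav,14
lim_dav,Deilephila elpenor,lim,dav,3
lim_dav,Deilephila elpenor,dav,lim,1
lim_dav,Trichoplusia intermixta,lim,lim,14
lim_dav,Trichoplusia intermixta,dav,dav,0
lim_dav,Trichoplusia intermixta,lim,dav,0
lim_dav,Trichoplusia intermixta,dav,lim,0
lim_del,Deilephila elpenor,lim,lim,8
lim_del,Deilephila elpenor,del,del,0
lim_del,Deilephila elpenor,lim,del,0
lim_del,Deilephila elpenor,del,lim,0
lim_del,Trichoplusia intermixta,lim,lim,2
lim_del,Trichoplusia intermixta,del,del,13
lim_del,Trichoplusia intermixta,lim,del,2
lim_del,Trichoplusia intermixta,del,lim,2
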