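era,term,with_traits,without_trait_slopes
1950s,species,2.029,1.708
1950s,species_phy,0,0
1950s,nested,0.368,0.622
1950s,site,0,0
1950s,zero_inflation,0.124,0.111
2000s,species,0,0
2000s,species_phy,0.286,0.270
2000s,nested,0.494,0.615
2000s,site,0,0
2000s,zero_inflation,0.061,0.068
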