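name,source_codes,max_dist_km,weight,decay
arable,1,8,0.8,exponential
reservoir,43,3,0.5,exponential
urban,51,6,0.75,exponential
rural_settlements,52,10,1,exponential
other_construction,53,1,0.4,linear
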