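code,name,aggregate
1,Arable land,arable
3,Grasslands,grassland
6,Unused lands,unused
21,Woodlands,woodland
22,Bush forests,woodland
23,Sparse woodlands,woodland
24,Other woodlands,woodland
41,Canals,water
43,Reservoir ponds,water
45,Tidal flats,water
46,Beaches,water
51,Urban lands,construction
52,Rural settlements,construction
53,Construction land,construction
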