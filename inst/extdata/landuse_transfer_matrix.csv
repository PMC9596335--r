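t0,t1,from,arable,woodland,grassland,water,construction,unused
1995,2000,arable,1837400,500,100,1600,900,0
1995,2000,woodland,2300,6025200,2000,500,0,0
1995,2000,grassland,100,4100,501400,100,0,0
1995,2000,water,100,0,0,136900,0,0
1995,2000,construction,0,0,0,100,165500,0
1995,2000,unused,0,0,100,0,100,300
2000,2010,arable,1826000,4900,0,2300,6700,0
2000,2010,woodland,200,6022400,1100,1700,4300,100
2000,2010,grassland,0,11800,491100,100,600,0
2000,2010,water,200,400,0,138500,100,0
2000,2010,construction,100,200,0,0,166200,0
2000,2010,unused,0,0,0,0,0,300
2010,2015,arable,1807700,300,100,600,17800,0
2010,2015,woodland,300,5992600,34400,200,12300,0
2010,2015,grassland,0,0,490000,0,2200,0
2010,2015,water,0,0,100,142000,500,0
2010,2015,construction,100,0,0,0,177800,0
2010,2015,unused,0,0,0,0,0,400
2015,2020,arable,904100,664900,88700,43300,106900,200
2015,2020,woodland,654000,5005400,218500,55700,59100,100
2015,2020,grassland,88500,244100,172000,8500,11400,100
2015,2020,water,42100,52100,7900,31800,8900,0
2015,2020,construction,97300,47900,7100,9700,48600,0
2015,2020,unused,300,100,0,0,0,0
1995,2020,arable,915500,671000,89600,46000,118200,200
1995,2020,woodland,655000,5033500,220500,56900,63900,100
1995,2020,grassland,89000,225100,170500,8400,12600,100
1995,2020,water,40400,50100,7600,30100,8800,0
1995,2020,construction,86200,34400,6000,7600,31400,0
1995,2020,unused,200,300,0,0,0,0
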