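raw,class,label
1,1,agriculture
2,2,coastal dune
3,3,coastal rock
4,4,deciduous forest
5,5,evergreen forest
6,6,grassland
7,7,modified land
8,8,savanna
9,9,shrubland
10,10,sparse vegetation
11,11,unsuitable habitat
12,12,wetland
13,1,agriculture
14,2,coastal dune
15,3,coastal rock
16,4,deciduous forest
17,5,evergreen forest
18,6,grassland
19,7,modified land
20,8,savanna
21,9,shrubland
22,10,sparse vegetation
23,11,unsuitable habitat
24,12,wetland
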