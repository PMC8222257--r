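species,Apis mellifera,Lasioglossum sp1,Episyrphus balteatus,Num. of hosts sampled
Leucopogon sp.,12,3,0,15
Grevillea acanthifolia,0,5,2,7
Epacris paludosa,4,0,1,5
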