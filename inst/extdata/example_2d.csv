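name,laterality,x,y
Poc,midline,10,0
Aoc,midline,30,0
Ar,midline,-25,40
SE,midline,0,50
PTM,midline,5,10
LT,midline,0,0
pra_fop_point,midline,-15,0
A,midline,45,25
B,midline,42,-15
SPr,midline,48,15
IPr,midline,46,-5
Me,midline,40,-20
corpus_lowest,midline,20,-22
ramus_posterior_most,midline,-22,20
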