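# The six snake mitogenome arrangements reported before the eleven-type
# comparison: the typical-minus-OL blind-snake order, the WQANCY
# blind-snake order, the standard alethinophidian duplicate-CR order, the
# viperid Pro-translocated order, its pseudo-Pro variant, and the
# colubrid/homalopsid pseudo-Pro order.
label	description	order
prior-1	blind snake, typical order without OL (ancestral candidate)	F,12S,V,16S,L2,ND1,I,-Q,M,ND2,W,-A,-N,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P,CR:1100
prior-2	blind snake, OL lost and Gln moved into WANCY	F,12S,V,16S,L2,ND1,I,M,ND2,W,-Q,-A,-N,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P,CR:1100
prior-3	alethinophidian duplicate control regions, Leu(UUR) translocated	F,12S,V,16S,ND1,I,CR:1100,L2,-Q,M,ND2,W,-A,-N,OL,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P,CR:1100
prior-4	viperid order, Pro at 5' of CR2	F,12S,V,16S,ND1,I,-P,CR:1100,L2,-Q,M,ND2,W,-A,-N,OL,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,CR:1100
prior-5	viperid order with pseudo-Pro at 5' of CR1	F,12S,V,16S,ND1,I,-P,CR:1100,L2,-Q,M,ND2,W,-A,-N,OL,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P*,CR:1100
prior-6	colubrid/homalopsid order with pseudo-Pro at 5' of CR2	F,12S,V,16S,ND1,I,-P*,CR:1100,L2,-Q,M,ND2,W,-A,-N,OL,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P,CR:1100
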