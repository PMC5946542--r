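# Reference gene orders for the eleven snake mitogenome arrangement types.
# Orders are written linearly from tRNA-Phe; "-" marks L-strand genes and
# ":len" carries the diagnostic control-region / non-coding lengths (bp).
# CR numbering convention: the control region immediately upstream of
# tRNA-Phe is CR1 (the typical vertebrate position); the control region in
# the rearranged ND1..ND2 segment is CR2. parent names the arrangement each
# type is derived from (UNKNOWN = indeterminate ancestral condition).
# asym_required marks the type whose sole diagnostic is control-region
# length asymmetry. The III-F control-region lengths are representative
# synthetic values (its published diagnostic is the 342 bp insertion plus
# asymmetric control regions, without printed sizes).
label	parent	asym_required	description	order
I	UNKNOWN	FALSE	single CR, OL lost, Gln translocated into the WANCY cluster (WQANCY)	F,12S,V,16S,L2,ND1,I,M,ND2,W,-Q,-A,-N,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P,CR:1100
II	UNKNOWN	FALSE	typical vertebrate order with OL lost from the WANCY cluster	F,12S,V,16S,L2,ND1,I,-Q,M,ND2,W,-A,-N,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P,CR:1100
III	UNKNOWN	FALSE	duplicated control regions with Leu(UUR) translocated downstream of CR2	F,12S,V,16S,ND1,I,CR:1100,L2,-Q,M,ND2,W,-A,-N,OL,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P,CR:1100
III-A	III	FALSE	Lys translocated from 3' of COX2 to 5' of ATP6	F,12S,V,16S,ND1,I,CR:1100,L2,-Q,M,ND2,W,-A,-N,OL,-C,-Y,COX1,-S2,D,COX2,ATP8,K,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P,CR:1100
III-B	III	FALSE	Pro translocated to 5' of CR2	F,12S,V,16S,ND1,I,-P,CR:1100,L2,-Q,M,ND2,W,-A,-N,OL,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,CR:1100
III-B1	III-B	FALSE	as III-B plus pseudo-Pro at 5' of CR1	F,12S,V,16S,ND1,I,-P,CR:1100,L2,-Q,M,ND2,W,-A,-N,OL,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P*,CR:1100
III-C	III	FALSE	pseudo-Pro inserted at 5' of CR2	F,12S,V,16S,ND1,I,-P*,CR:1100,L2,-Q,M,ND2,W,-A,-N,OL,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P,CR:1100
III-D	III	FALSE	additional tRNA-Ile copy inserted at 5' of CR1	F,12S,V,16S,ND1,I,CR:1100,L2,-Q,M,ND2,W,-A,-N,OL,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P,I,CR:1100
III-E	III	TRUE	prolonged asymmetric control regions (2878 bp CR1, 4110 bp CR2)	F,12S,V,16S,ND1,I,CR:4110,L2,-Q,M,ND2,W,-A,-N,OL,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P,CR:2878
III-F	III	FALSE	342 bp non-coding insertion between ND5 and ND6 plus asymmetric control regions	F,12S,V,16S,ND1,I,CR:2905,L2,-Q,M,ND2,W,-A,-N,OL,-C,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,NC:342,-ND6,-E,CYTB,T,-P,CR:1984
III-G	III	FALSE	5702 bp non-coding insertion between Cys and Tyr	F,12S,V,16S,ND1,I,CR:1100,L2,-Q,M,ND2,W,-A,-N,OL,-C,NC:5702,-Y,COX1,-S2,D,COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P,CR:1100
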