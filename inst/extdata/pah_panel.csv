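# Default targeted PAH panel: US-EPA 16 priority PAHs + retene,
# benzo[e]pyrene, perylene. benzene_rings counts six-membered aromatic
# rings only (fluoranthene: 3 benzene rings + one five-membered ring).
# loq in ng/g dry weight; is_partner = deuterated internal standard.
name,abbreviation,benzene_rings,mw,iarc,is_partner,loq
naphthalene,Nap,2,128.17,2B,naphthalene-d8,5
acenaphthylene,Acy,2,152.19,NA,acenaphthene-d10,5
acenaphthene,Ace,2,154.21,3,acenaphthene-d10,5
fluorene,Fle,2,166.22,3,acenaphthene-d10,5
phenanthrene,Phe,3,178.23,3,phenanthrene-d10,5
anthracene,Ant,3,178.23,3,phenanthrene-d10,5
fluoranthene,Flt,3,202.25,3,phenanthrene-d10,5
pyrene,Pyr,4,202.25,3,phenanthrene-d10,5
benz[a]anthracene,BaA,4,228.29,2B,chrysene-d12,5
chrysene,Chr,4,228.29,2B,chrysene-d12,5
benzo[b]fluoranthene,BbF,4,252.31,2B,perylene-d12,5
benzo[k]fluoranthene,BkF,4,252.31,2B,perylene-d12,5
benzo[a]pyrene,BaP,5,252.31,1,perylene-d12,5
"indeno[1,2,3-cd]pyrene",IcdP,5,276.33,2B,perylene-d12,5
"dibenz[a,h]anthracene",DahA,5,278.35,2A,perylene-d12,5
benzo[ghi]perylene,BghiP,6,276.33,3,perylene-d12,5
retene,Ret,3,234.34,NA,phenanthrene-d10,5
benzo[e]pyrene,BeP,5,252.31,3,perylene-d12,5
perylene,Per,5,252.31,3,perylene-d12,5
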