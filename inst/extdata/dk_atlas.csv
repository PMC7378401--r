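roi_index,name,abbrev,hemisphere,lobe
0,Bankssts L,lBKS,L,temporal
1,Caudal anterior cingulate L,lCAC,L,cingulate
2,Caudal middle frontal L,lCMF,L,frontal
3,Cuneus L,lCUN,L,occipital
4,Entorhinal L,lENT,L,temporal
5,Frontal pole L,lFP,L,frontal
6,Fusiform L,lFUS,L,temporal
7,Inferior parietal L,lIP,L,parietal
8,Inferior temporal L,lIT,L,temporal
9,Insula L,lINS,L,insula
10,Isthmus cingulate L,lIST,L,cingulate
11,Lateral occipital L,lLO,L,occipital
12,Lateral orbitofrontal L,lLOF,L,frontal
13,Lingual L,lLING,L,occipital
14,Medial orbitofrontal L,lMOF,L,frontal
15,Middle temporal L,lMT,L,temporal
16,Para hippocampal L,lPHIP,L,temporal
17,Paracentral L,lPARAC,L,frontal
18,Pars opercularis L,lPOP,L,frontal
19,Pars orbitalis L,lPOR,L,frontal
20,Pars triangularis L,lPT,L,frontal
21,Pericalcarine L,lPERI,L,occipital
22,Postcentral L,lPOC,L,parietal
23,Posterior cingulate L,lPC,L,cingulate
24,Precentral L,lPRC,L,frontal
25,Precuneus L,lPREC,L,parietal
26,Rostral anterior cingulate L,lRAC,L,cingulate
27,Rostral middle frontal L,lRMF,L,frontal
28,Superior frontal L,lSF,L,frontal
29,Superior parietal L,lSP,L,parietal
30,Superior temporal L,lST,L,temporal
31,Supramarginal L,lSMAR,L,parietal
32,Temporal pole L,lTP,L,temporal
33,Transverse temporal L,lTRANS,L,temporal
34,Bankssts R,rBKS,R,temporal
35,Caudal anterior cingulate R,rCAC,R,cingulate
36,Caudal middle frontal R,rCMF,R,frontal
37,Cuneus R,rCUN,R,occipital
38,Entorhinal R,rENT,R,temporal
39,Frontal pole R,rFP,R,frontal
40,Fusiform R,rFUS,R,temporal
41,Inferior parietal R,rIP,R,parietal
42,Inferior temporal R,rIT,R,temporal
43,Insula R,rINS,R,insula
44,Isthmus cingulate R,rIST,R,cingulate
45,Lateral occipital R,rLO,R,occipital
46,Lateral orbitofrontal R,rLOF,R,frontal
47,Lingual R,rLING,R,occipital
48,Medial orbitofrontal R,rMOF,R,frontal
49,Middle temporal R,rMT,R,temporal
50,Para hippocampal R,rPHIP,R,temporal
51,Paracentral R,rPARAC,R,frontal
52,Pars opercularis R,rPOP,R,frontal
53,Pars orbitalis R,rPOR,R,frontal
54,Pars triangularis R,rPT,R,frontal
55,Pericalcarine R,rPERI,R,occipital
56,Postcentral R,rPOC,R,parietal
57,Posterior cingulate R,rPC,R,cingulate
58,Precentral R,rPRC,R,frontal
59,Precuneus R,rPREC,R,parietal
60,Rostral anterior cingulate R,rRAC,R,cingulate
61,Rostral middle frontal R,rRMF,R,frontal
62,Superior frontal R,rSF,R,frontal
63,Superior parietal R,rSP,R,parietal
64,Superior temporal R,rST,R,temporal
65,Supramarginal R,rSMAR,R,parietal
66,Temporal pole R,rTP,R,temporal
67,Transverse temporal R,rTRANS,R,temporal
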