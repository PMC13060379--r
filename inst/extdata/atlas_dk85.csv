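index,name,hemisphere,lobe,pair_index
0,lh_bankssts,left,temporal,0
1,lh_caudalanteriorcingulate,left,cingulate,1
2,lh_caudalmiddlefrontal,left,frontal,2
3,lh_cuneus,left,occipital,3
4,lh_entorhinal,left,temporal,4
5,lh_frontalpole,left,frontal,5
6,lh_fusiform,left,temporal,6
7,lh_inferiorparietal,left,parietal,7
8,lh_inferiortemporal,left,temporal,8
9,lh_insula,left,insula,9
10,lh_isthmuscingulate,left,cingulate,10
11,lh_lateraloccipital,left,occipital,11
12,lh_lateralorbitofrontal,left,frontal,12
13,lh_lingual,left,occipital,13
14,lh_medialorbitofrontal,left,frontal,14
15,lh_middletemporal,left,temporal,15
16,lh_paracentral,left,frontal,16
17,lh_parahippocampal,left,temporal,17
18,lh_parsopercularis,left,frontal,18
19,lh_parsorbitalis,left,frontal,19
20,lh_parstriangularis,left,frontal,20
21,lh_pericalcarine,left,occipital,21
22,lh_postcentral,left,parietal,22
23,lh_posteriorcingulate,left,cingulate,23
24,lh_precentral,left,frontal,24
25,lh_precuneus,left,parietal,25
26,lh_rostralanteriorcingulate,left,cingulate,26
27,lh_rostralmiddlefrontal,left,frontal,27
28,lh_superiorfrontal,left,frontal,28
29,lh_superiorparietal,left,parietal,29
30,lh_superiortemporal,left,temporal,30
31,lh_supramarginal,left,parietal,31
32,lh_temporalpole,left,temporal,32
33,lh_transversetemporal,left,temporal,33
34,rh_bankssts,right,temporal,0
35,rh_caudalanteriorcingulate,right,cingulate,1
36,rh_caudalmiddlefrontal,right,frontal,2
37,rh_cuneus,right,occipital,3
38,rh_entorhinal,right,temporal,4
39,rh_frontalpole,right,frontal,5
40,rh_fusiform,right,temporal,6
41,rh_inferiorparietal,right,parietal,7
42,rh_inferiortemporal,right,temporal,8
43,rh_insula,right,insula,9
44,rh_isthmuscingulate,right,cingulate,10
45,rh_lateraloccipital,right,occipital,11
46,rh_lateralorbitofrontal,right,frontal,12
47,rh_lingual,right,occipital,13
48,rh_medialorbitofrontal,right,frontal,14
49,rh_middletemporal,right,temporal,15
50,rh_paracentral,right,frontal,16
51,rh_parahippocampal,right,temporal,17
52,rh_parsopercularis,right,frontal,18
53,rh_parsorbitalis,right,frontal,19
54,rh_parstriangularis,right,frontal,20
55,rh_pericalcarine,right,occipital,21
56,rh_postcentral,right,parietal,22
57,rh_posteriorcingulate,right,cingulate,23
58,rh_precentral,right,frontal,24
59,rh_precuneus,right,parietal,25
60,rh_rostralanteriorcingulate,right,cingulate,26
61,rh_rostralmiddlefrontal,right,frontal,27
62,rh_superiorfrontal,right,frontal,28
63,rh_superiorparietal,right,parietal,29
64,rh_superiortemporal,right,temporal,30
65,rh_supramarginal,right,parietal,31
66,rh_temporalpole,right,temporal,32
67,rh_transversetemporal,right,temporal,33
68,lh_thalamus,left,subcortical,34
69,lh_caudate,left,subcortical,35
70,lh_putamen,left,subcortical,36
71,lh_pallidum,left,subcortical,37
72,lh_hippocampus,left,subcortical,38
73,lh_amygdala,left,subcortical,39
74,lh_accumbens,left,subcortical,40
75,lh_ventraldc,left,subcortical,41
76,rh_thalamus,right,subcortical,34
77,rh_caudate,right,subcortical,35
78,rh_putamen,right,subcortical,36
79,rh_pallidum,right,subcortical,37
80,rh_hippocampus,right,subcortical,38
81,rh_amygdala,right,subcortical,39
82,rh_accumbens,right,subcortical,40
83,rh_ventraldc,right,subcortical,41
84,brainstem,midline,brainstem,NA
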