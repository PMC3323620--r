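patient	nup	age_years	sex	clinical_features
1	1506614	7.9	F	bone
2	1506751	9	M	bone
3	2106401	0.26	M	skin, lung, lymph node
4	2106143	0.5	M	LETTERER SIWE hematological dysfunction, bone, liver, spleen
5	1406259	8.4	F	bone
6	1506706	19	M	Skin
7	2106169	0.438	F	LETTERER SIWE hematological dysfunction, bone, liver, spleen, pituitary
8	1406253	8.6	F	bone
9	1406254	7.6	M	bone
10	1406015	0	F	LETTERER SIWE hematological dysfunction, bone, liver, spleen, pituitary, lung, lymph nodes
11	1406210	10	M	bone
12	1506008	0.97	F	LETTERER SIWE hematological dysfunction, bone, lung, liver, spleen
13	1406215	5.3	M	bone
14	1406247	7.59	F	bone, lymph node
15	1506766	11.79	F	bone
16	1506646	1	M	skin, bone
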