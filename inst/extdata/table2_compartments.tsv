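patient	compartment	allele	rma_percent
1	granuloma_total_gDNA	V600E	13.5
1	whole_blood	wt
1	CD14pos	wt
1	CD14neg	wt
2	granuloma_total_gDNA	V600E	29.4
2	whole_blood	wt
3	granuloma_total_gDNA	V600E	16
4	CD1a_gDNA	V600E	35
4	CD1a_cDNA	V600E	40
5	CD1a_gDNA	V600E	38
5	effluent_gDNA	V600E	22
5	CD1a_cDNA	V600E	46
5	effluent_cDNA	V600E	24
6	granuloma_total_gDNA	V600E	8
7	granuloma_total_gDNA	V600E	9
8	CD1a_gDNA	V600E	21
8	effluent_gDNA	V600E	8
8	CD1a_cDNA	V600E	48
8	effluent_cDNA	V600E	6
9	CD1a_gDNA	V600E	35
9	effluent_gDNA	V600E	23
9	CD1a_cDNA	V600E	47
9	effluent_cDNA	V600E	35
10	CD1a_gDNA	600DLAT	11
10	effluent_gDNA	600DLAT	5
10	CD1a_cDNA	600DLAT	28
10	effluent_cDNA	600DLAT	11
11	granuloma_total_gDNA	wt
12	granuloma_total_gDNA	wt
13	granuloma_total_gDNA	wt
14	granuloma_total_gDNA	wt
15	granuloma_total_gDNA	wt
15	CD14pos	wt
15	CD14neg	wt
16	granuloma_total_gDNA	T599A	44
16	whole_blood	T599A	37
16	CD14pos	T599A	37
16	CD14neg	T599A	45
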