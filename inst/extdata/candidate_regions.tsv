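vista_id	query_chrom	query_start	query_end	size_nt	target_chrom	target_start	target_end	flank_status	rank
hs1344	3	193660817	193662478	1662	4	13569031	13570692	DF	2
hs865	6	50685244	50686237	994	24	19553675	19554668	DF	4
hs1535	2	60498057	60502013	3957	15	7226825	7230781	DF	7
hs848	16	51491799	51493025	1227	3	29251639	29252865	SF	1
hs1049	5	92314781	92316083	1303	9	15278121	15279423	SF	1
hs882	13	71533037	71534195	1159	21	9408987	9410145	SF	1
hs1831	7	95236622	95240458	3837	11	9757778	9761614	SF	3
hs590	18	34719386	34720720	1335	5	16698603	16699937	SF	9
hs394	2	59746377	59746992	616	15	7017013	7017628	DF	23
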