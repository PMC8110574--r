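chromosome	total_genes	genes_in_blocks	n_blocks	genes_largest_block
1	2436	2235	25	426
2	3246	2810	23	677
3	2618	2574	6	2297
4	2234	1684	11	403
5	2958	2373	13	746
6	3427	2582	19	906
7	2478	2206	15	1523
8	3923	3298	29	600
9	1792	1463	13	422
10	2099	1874	19	335
11	2497	2258	17	710
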