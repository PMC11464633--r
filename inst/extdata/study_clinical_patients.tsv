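patient	age	sex	burn_type	severity	hads_anx_first	hads_anx_last	hads_dep_first	hads_dep_last
1	36	Male	Thermal	1	9	4	7	2
2	20	Male	Thermal	1	9	8	3	2
3	65	Male	Electric	2	2	2	3	0
4	29	Male	Thermal	1	7	6	7	1
5	18	Female	Thermal	1	11	9	6	9
6	19	Male	Thermal	1	7	1	4	1
7	58	Male	Electric	2	0	1	0	2
8	28	Male	Thermal	1	2	1	0	0
9	29	Male	Electric	2	4	NA	2	NA
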