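patient	session	vas_pre	vas_post
1	1	0	0
1	2	7	4
2	1	3	0
2	2	4	6
3	1	0	0
3	2	0	0
4	1	2	0
4	2	8	7
5	1	3	2
5	2	0	1
6	1	0	0
6	2	0	0
7	1	2	0
7	2	0	0
8	1	1	0
8	2	4	0
9	1	0	1
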