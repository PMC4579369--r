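id	ad	sa	control
1001	48	30	164
1002	28	27	131
1003	32	30	95
1004	7	8	41
1005	6	3	47
1006	4	11	33
1007	11	5	21
1008	0	0	16
1009	0	0	15
1010	0	0	10
1011	3	2	15
1012	3	2	1
1013	0	0	6
1014	0	0	6
1015	0	0	2
1016	0	0	7
1017	1	0	4
1019	0	0	5
1021	0	0	1
1023	0	0	1
1024	0	1	0
1026	0	1	0
1029	1	0	2
1030	1	0	3
1039	0	0	1
1041	0	0	1
1042	0	2	0
1045	2	0	0
1057	1	0	0
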