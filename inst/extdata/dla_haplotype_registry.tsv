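region	id	tuple	frequency	mini_only	exon2
dla_class_I	1001	380/373/281/182	0.259	0	NA
dla_class_I	1002	380/365/281/181	0.2	0	NA
dla_class_I	1003	387/375/277/186	0.157	0	NA
dla_class_I	1004	393/379/277/183	0.09	0	NA
dla_class_I	1005	389/371/277/181	0.056	0	NA
dla_class_I	1006	387/375/293/180	0.043	0	NA
dla_class_I	1007	380/372/281/182	0.031	0	NA
dla_class_I	1008	386/373/289/182	0.018	0	NA
dla_class_I	1009	382/377/277/184	0.011	0	NA
dla_class_I	1010	384/371/277/186	0.016	0	NA
dla_class_I	1011	376/365/281/180	0.02	0	NA
dla_class_I	1012	388/369/289/188	0.011	0	NA
dla_class_I	1013	392/373/289/186	0.01	0	NA
dla_class_I	1014	375/373/287/178	0.008	0	NA
dla_class_I	1015	380/373/291/186	0.003	0	NA
dla_class_I	1016	382/371/277/178	0.005	0	NA
dla_class_I	1017	386/373/289/178	0.005	0	NA
dla_class_I	1018	375/373/287/186	0.013	1	NA
dla_class_I	1019	380/373/287/185	0.003	0	NA
dla_class_I	1020	388/369/289/184	0.004	1	NA
dla_class_I	1021	380/373/289/186	0.003	0	NA
dla_class_I	1022	380/375/281/181	0.001	0	NA
dla_class_I	1023	380/379/281/181	0.001	0	NA
dla_class_I	1024	387/373/281/182	0.001	0	NA
dla_class_I	1026	390/369/289/186	0.001	0	NA
dla_class_I	1027	391/371/277/181	0.001	0	NA
dla_class_I	1028	376/369/291/186	0.001	1	NA
dla_class_I	1029	380/365/281/182	0.003	0	NA
dla_class_I	1030	380/373/293/178	0.006	0	NA
dla_class_I	1031	382/371/277/186	0.003	1	NA
dla_class_I	1032	382/377/277/178	0.001	1	NA
dla_class_I	1033	382/379/277/181	0.001	1	NA
dla_class_I	1034	382/379/277/182	0.001	1	NA
dla_class_I	1035	386/373/277/184	0.001	0	NA
dla_class_I	1036	389/365/289/180	0.002	1	NA
dla_class_I	1039	379/364/281/181	0.001	0	NA
dla_class_I	1040	380/371/277/186	0.001	1	NA
dla_class_I	1041	386/374/277/186	0.001	0	NA
dla_class_I	1042	389/375/293/186	0.001	0	NA
dla_class_I	1043	393/381/277/183	0.001	0	NA
dla_class_I	1045	376/371/277/186	0.001	0	NA
dla_class_I	1046	376/379/291/180	0.001	0	NA
dla_class_I	1057	387/376/277/186	0.001	0	NA
dla_class_II	2001	343/324/284	0.605	0	01501/00601/02301
dla_class_II	2002	343/327/280	0.091	0	01501/00901/00101
dla_class_II	2003	343/324/282	0.092	0	01503/00601/02301
dla_class_II	2004	351/327/268	0.027	0	02001/00401/01303
dla_class_II	2005	339/322/280	0.024	0	00101/00101/00201,00901/00101/00801
dla_class_II	2006	339/325/280	0.032	0	01502/00601/02301
dla_class_II	2007	351/327/280	0.016	0	02001/00401/01303
dla_class_II	2008	339/327/276	0.011	0	00101/00101/03601
dla_class_II	2009	351/324/280	0.016	0	NA
dla_class_II	2010	345/329/280	0.016	0	01201/00401/01301
dla_class_II	2011	345/322/284	0.02	0	00901/00101/00801
dla_class_II	2012	345/322/280	0.008	0	00901/00101/00801
dla_class_II	2013	345/327/284	0.008	0	00201/00901/00101
dla_class_II	2014	339/322/284	0.005	0	NA
dla_class_II	2015	339/327/280	0.005	1	NA
dla_class_II	2016	339/323/284	0.003	0	00601/05011/00701
dla_class_II	2017	343/322/280	0.004	0	NA
dla_class_II	2018	339/324/284	0.001	0	00601/05011/00701
dla_class_II	2019	345/324/284	0.001	0	NA
dla_class_II	2020	349/324/284	0.001	0	NA
dla_class_II	2021	339/324/268	0.001	1	NA
dla_class_II	2022	339/327/282	0.001	0	NA
dla_class_II	2023	341/323/282	0.006	0	NA
dla_class_II	2024	343/323/280	0.001	1	NA
dla_class_II	2025	351/321/280	0.002	1	NA
dla_class_II	2026	351/324/284	0.001	0	NA
dla_class_II	2027	343/325/284	0.001	0	NA
dla_class_II	2028	345/327/288	0.001	1	NA
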