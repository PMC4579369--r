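id	ad	sa	control
2001	109	87	384
2002	7	8	41
2003	9	5	54
2004	3	9	16
2005	1	0	20
2006	12	5	21
2007	1	2	17
2008	0	0	15
2009	0	1	8
2010	0	0	10
2011	3	2	15
2012	2	1	2
2013	0	0	6
2014	0	0	7
2016	0	0	4
2017	0	0	1
2018	0	0	1
2019	0	0	1
2020	0	2	0
2023	1	0	3
2026	0	0	0
2027	0	0	2
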