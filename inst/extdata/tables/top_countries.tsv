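crude_rank	country	nationality	continent	articles	population
1	United States	American	North America	2922	2120277
2	United Kingdom	British	Europe	993	88274
3	Australia	Australian	Oceania	730	30685
4	Canada	Canadian	North America	498	38321
5	China	Chinese	Asia	371	1627290
6	Germany	German	Europe	340	68437
7	France	French	Europe	281	62158
8	Sweden	Swedish	Europe	261	6510
9	India	Indian	Asia	249	385832
10	Netherlands	Dutch	Europe	249	14470
11	Italy	Italian	Europe	227	56090
12	Japan	Japanese	Asia	202	65348
13	Spain	Spanish	Europe	193	61751
14	Brazil	Brazilian	South America	162	509602
15	South Africa	South African	Africa	146	164629
16	Norway	Norwegian	Europe	138	3289
17	Switzerland	Swiss	Europe	135	6257
18	Finland	Finnish	Europe	135	3238
19	Denmark	Danish	Europe	125	3729
20	South Korea	South Korean	Asia	94	52989
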