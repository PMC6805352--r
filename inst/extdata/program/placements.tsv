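name	az_deg	pol_deg
1a-2	230.1	67.7
1b-2	320.1	67.7
1c-2	50.1	67.7
1d-2	140.1	67.7
1a-21	218	58.5
1b-21	308	58.5
1c-21	38	58.5
1d-21	128	58.5
1a-22	239.3	77.1
1b-22	329.3	77.1
1c-22	59.3	77.1
1d-22	149.3	77.1
1c-1121222	85	30
1c-1121122	50	28
1a-1121122	242	20
1a-1121212	200	34
1b-112111	320	26
1b-112122	290	45
1c-12111	12	64
1c-12112	15	62
1c-121121	10	66
1c-121122	22	68
1c-121121a	18	70
1c-121121b	6	72
1a-12111	168	64
1a-12112	165	62
1a-121121	170	66
1a-121122	158	68
1a-1211212	162	70
1a-1211211	174	72
1b-1211	295	50
1b-12111	305	54
1b-12112	283	55
1b-12111a	303	57
1b-121121	278	50
1b-12111b	310	58
1b-12111ab	300	55
1b-121122	285	60
1b-121121a	275	52
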