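pair_id	left	right	origin	cycle_h	depth	az_deg	pol_deg	class	verified
1	1d-112111	1c-112121	10	5	4	80	22	non_corresponding	FALSE
2	1d-112112	1c-1121221	10.6	5.2	3	35	32	non_corresponding	FALSE
3	1d-112121	1c-112111	12	4.8	4	60	45	non_corresponding	FALSE
4	1d-1122	1c-1122	6	3.4	7	80	62	quadrant_homolog	TRUE
5	1d-112122	1c-1121121	12.6	5	3	25	52	non_corresponding	FALSE
6	1a-1211	1c-1211	8	NA	0	0	58	ac_homolog	TRUE
7	1a-112111	1b-112121	10.2	5.4	3	-75	25	non_corresponding	FALSE
8	1a-112122	1b-112112	10.6	5.6	3	-40	32	non_corresponding	FALSE
9	1a-1122	1b-1122	6	3.6	6	-80	62	quadrant_homolog	TRUE
10	1a-1121121	1a-1121211	12	5.8	3	-60	45	single_quadrant	TRUE
11	1b-12111aa	1b-121121b	15.5	4.6	3	-25	52	single_quadrant	TRUE
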