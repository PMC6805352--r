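mother	quadrants	time	mode	d1	d2	d1_tag	d2_tag
1m	abcd	3	spiral_cw	1	2	none	none
1m-2	abcd	4	spiral_ccw	1	2	none	none
1m-1	abcd	4.5	spiral_ccw	1	2	none	none
1m-11	abcd	5	spiral_cw	1	2	none	none
1m-21	abcd	6.5	radial	1	2	accessory_prototroch	primary_prototroch
1m-22	abcd	7	radial	1	2	primary_prototroch	primary_prototroch
1m-12	abc	7	spiral_cw	1	2	none	accessory_prototroch
1d-12	-	7	spiral_cw	1	2	migrates_out	none
1m-121	abc	8	spiral_ccw	1	2	none	accessory_prototroch
1d-122	-	8	spiral_ccw	1	2	accessory_prototroch	migrates_out
1m-112	abcd	6	bilateral	1	2	none	none
1m-1121	abcd	8	bilateral	1	2	none	none
1c-111	-	9	radial	1	2	apical_organ	apical_organ
1d-111	-	10	radial	1	2	apical_organ	apical_organ
1a-111	-	9	budding	1	2	none	apical_organ
1a-1111	-	12	radial	1	2	apical_organ	none
1a-11112	-	17.5	bilateral	a	b	none	none
1a-11112a	-	23	bilateral	a	b	none	none
1a-11112b	-	23	bilateral	a	b	none	none
1d-11211	-	10.6	bilateral	1	2	none	none
1d-11212	-	12.6	bilateral	1	2	none	none
1c-11212	-	10	bilateral	1	2	none	none
1c-112122	-	11.4	bilateral	1	2	none	terminal
1c-11211	-	12	bilateral	1	2	none	none
1c-112112	-	13.4	bilateral	1	2	none	terminal
1a-11211	-	10.2	bilateral	1	2	none	none
1a-112112	-	12	bilateral	1	2	none	terminal
1a-11212	-	10.6	bilateral	1	2	none	none
1a-112121	-	12.2	bilateral	1	2	none	terminal
1b-11212	-	10.8	bilateral	1	2	none	terminal
1b-11211	-	11.2	bilateral	1	2	terminal	none
1m-1211	ac	10.5	bilateral	1	2	apoptotic	none
1m-12112	ac	13	bilateral	1	2	none	terminal
1a-121121	-	16	bilateral	1	2	terminal	terminal
1c-121121	-	16	bilateral	a	b	terminal	terminal
1b-1211	-	10.5	bilateral	1	2	none	none
1b-12111	-	13	bilateral	a	b	none	terminal
1b-12111a	-	15.5	bilateral	a	b	none	terminal
1b-12112	-	13	bilateral	1	2	none	terminal
1b-121121	-	15.5	bilateral	a	b	terminal	none
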