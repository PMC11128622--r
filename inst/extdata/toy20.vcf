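##fileformat=VCFv4.2
##INFO=<ID=DP,Number=1,Type=Float,Description="depth">
##FORMAT=<ID=GT,Number=1,Type=String,Description="genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4
1	100	rs01	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=1;GENE=G01;IMPACT=HIGH;AF_1KG_EUR=0.001	GT	0/0	0/1	1/1	0/0
1	200	rs02	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=1;GENE=G02;IMPACT=LOW;CADD_PHRED=20	GT	0/0	0/1	1/1	0/0
1	300	rs03	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=1;GENE=G03;IMPACT=MODIFIER;AF_1KG_EUR=0.005	GT	0/0	0/1	1/1	0/0
1	400	rs04	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=1;GENE=G04;IMPACT=LOW;CADD_PHRED=15;AF_1KG_EUR=0.009;AF_EXAC=0.0001	GT	0/0	0/1	1/1	0/0
1	500	rs05	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=1;GENE=G05;IMPACT=MODERATE;AF_1KG_EUR=0.0	GT	0/0	0/1	1/1	0/0
1	600	rs06	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=1;GENE=G06;IMPACT=LOW;CADD_PHRED=14.99;AF_1KG_EUR=0.005	GT	0/0	0/1	1/1	0/0
1	700	rs07	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=1;GENE=G07;IMPACT=HIGH;AF_1KG_EUR=0.01	GT	0/0	0/1	1/1	0/0
1	800	rs08	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=1;GENE=G08;IMPACT=HIGH;AF_EXAC=0.2	GT	0/0	0/1	1/1	0/0
1	900	rs09	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=1;GENE=G09	GT	0/0	0/1	1/1	0/0
1	1000	rs10	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=1;GENE=G10;CADD_PHRED=30;AF_1KG_EUR=0.005	GT	0/0	0/1	1/1	0/0
1	1100	rs11	A	G	.	PASS	DP=12;MQ=30;QD=2;FS=25;GENE=G11;IMPACT=MODERATE;AF_1KG_EUR=0.002	GT	0/0	0/1	1/1	0/0
1	1200	rs12	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=1;GENE=G12;AF_1KG_EUR=0.5	GT	0/0	0/1	1/1	0/0
1	1300	rs13	A	G	.	PASS	DP=11;MQ=60;QD=20;FS=1;GENE=G13;IMPACT=HIGH;AF_1KG_EUR=0.001	GT	0/0	0/1	1/1	0/0
1	1400	rs14	A	G	.	PASS	DP=50;MQ=29.9;QD=20;FS=1;GENE=G14;IMPACT=HIGH;AF_1KG_EUR=0.001	GT	0/0	0/1	1/1	0/0
1	1500	rs15	A	G	.	PASS	DP=50;MQ=60;QD=1.99;FS=1;GENE=G15;IMPACT=HIGH;AF_1KG_EUR=0.001	GT	0/0	0/1	1/1	0/0
1	1600	rs16	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=25.01;GENE=G16;IMPACT=HIGH;AF_1KG_EUR=0.001	GT	0/0	0/1	1/1	0/0
1	1700	rs17	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=1;GENE=G17;IMPACT=HIGH;AF_1KG_EUR=0.001	GT	0/0	0/1	1/1	./.
1	1800	rs18	A	G	.	PASS	MQ=60;QD=20;FS=1;GENE=G18;IMPACT=HIGH;AF_1KG_EUR=0.001	GT	0/0	0/1	1/1	0/0
1	1900	rs19	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=30;GENE=G19;IMPACT=HIGH;AF_1KG_EUR=0.001	GT	0/0	0/1	1/1	0/0
1	2000	rs20	A	G	.	PASS	DP=50;MQ=60;QD=20;FS=1;GENE=G20;IMPACT=MODIFIER;AF_1KG_EUR=0.009	GT	0/0	0/1	1/1	0/0
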