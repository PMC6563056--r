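system	pair	bound_A	md_avg_A	md_err_A	leus_avg_A	leus_err_A
1	d(HT,H)	2.9	3.4	0.02	3.4	0.2
1	d(HA,HT)	2.3	2.3	0.01	2.3	0.06
1	d(HA,H)	2.9	2.6	0.02	2.7	0.2
1	d(HT,HB1)	2.5	3.5	0.01	3.2	0.2
1	d(HT,HB2)	2.6	3.2	0.06	3.1	0.2
1	d(H1,HA)	3.9	3.8	0.01	3.7	0.6
2	d(HT,H)	2.8	3.8	0.03	4.0	0.6
2	d(HA,HT)	2.4	2.2	0.3	2.2	0.6
2	d(HA,H)	2.9	2.8	0.01	2.7	0.03
2	d(HT,HB)	2.8	3.2	0.01	2.8	0.1
2	d(H,HB)	3.5	3.0	0.2	3.4	0.4
2	d(H,HN2)	3.3	4.0	0.06	3.4	0.3
3	d(HT,H)	2.9	3.4	0.03	3.6	0.2
3	d(HA,HT)	2.2	2.3	0.01	2.3	0.00
3	d(HA,H)	2.6	2.6	0.04	2.7	0.1
3	d(HT,HB1)	2.6	3.4	0.01	3.4	0.2
3	d(HT,HB2)	2.8	3.3	0.04	3.4	0.3
4	d(HT,H)	3.0	3.4	0.02	3.1	0.1
4	d(HA,HT)	2.3	2.3	0.01	2.3	0.06
4	d(HA,H)	2.8	2.7	0.01	2.7	0.1
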