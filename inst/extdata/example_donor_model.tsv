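pos	A	C	G	T
1	0.32	0.36	0.17	0.15
2	0.62	0.11	0.12	0.15
3	0.09	0.03	0.80	0.08
4	0.00	0.00	1.00	0.00
5	0.00	0.00	0.00	1.00
6	0.59	0.03	0.28	0.10
7	0.71	0.08	0.12	0.09
8	0.07	0.06	0.82	0.05
9	0.16	0.15	0.19	0.50
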