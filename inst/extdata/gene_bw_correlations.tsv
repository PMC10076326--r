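gene	tissue	r_abs	p_abs	r_slope	p_slope	published_selected
Cldn22	eWAT	0.83	0.04	0.72	0.11	TRUE
Prkag3	eWAT	0.81	0.05	0.65	0.17	TRUE
Scpep1	eWAT	0.74	0.09	0.59	0.22	TRUE
Srpx2	eWAT	0.71	0.11	0.53	0.27	TRUE
Mfsd7a	eWAT	0.70	0.12	0.56	0.25	TRUE
Sfrp5	eWAT	0.69	0.13	0.54	0.27	FALSE
Duoxa1	eWAT	0.66	0.15	0.52	0.29	FALSE
Zdhhc2	eWAT	0.65	0.16	0.51	0.30	FALSE
B430212C06Rik	eWAT	0.65	0.17	0.53	0.28	FALSE
Syp	eWAT	0.64	0.17	0.46	0.35	FALSE
Tmem45b	eWAT	0.64	0.17	0.51	0.30	FALSE
Aldh9a1	eWAT	0.62	0.19	0.51	0.30	FALSE
Dap	eWAT	0.23	0.66	0.12	0.83	FALSE
Cpne2	iWAT	-0.35	0.49	0.33	0.52	FALSE
Pus10	iWAT	-0.30	0.56	-0.30	0.56	FALSE
Gabrr2	iWAT	-0.24	0.65	-0.29	0.58	FALSE
Lox	BAT	0.96	<0.01	0.92	0.01	TRUE
Tgm2	BAT	0.91	0.01	0.84	0.03	TRUE
Gpx8	BAT	0.42	0.40	0.23	0.66	FALSE
Or7d12-ps1	liver	-0.96	<0.01	-0.95	<0.01	TRUE
Cryl1	liver	0.85	0.03	0.90	0.01	TRUE
Pepd	liver	0.79	0.06	0.85	0.03	TRUE
Cblc	liver	0.77	0.07	0.69	0.13	TRUE
Apoa4	liver	0.68	0.14	0.70	0.12	TRUE
Wfdc2	liver	0.45	0.37	0.36	0.49	FALSE
Sephs2	liver	0.38	0.46	0.47	0.35	FALSE
Pyroxd2	liver	0.32	0.54	0.12	0.82	FALSE
Pyroxd2	liver	0.32	0.54	0.12	0.82	FALSE
Ephx1	liver	0.31	0.54	0.23	0.67	FALSE
Tex2	liver	-0.27	0.60	-0.44	0.38	FALSE
Coq8a	liver	-0.26	0.61	-0.31	0.55	FALSE
Unc119	liver	0.26	0.62	0.04	0.93	FALSE
Plin2	liver	0.23	0.66	0.05	0.93	FALSE
L2hgdh	liver	0.23	0.67	0.13	0.80	FALSE
Nars2	liver	0.19	0.71	0.21	0.68	FALSE
Atp9a	liver	0.19	0.72	0.01	0.98	FALSE
Acp5	liver	0.19	0.72	0.33	0.53	FALSE
Serinc2	liver	-0.10	0.85	-0.26	0.61	FALSE
Cyp3a44	liver	0.09	0.86	-0.07	0.90	FALSE
Cyp3a11	liver	0.09	0.87	-0.07	0.89	FALSE
P2ry1	liver	-0.08	0.88	-0.18	0.74	FALSE
Cyp3a41b	liver	0.08	0.88	-0.08	0.88	FALSE
Serpina6	liver	0.08	0.88	0.00	1.00	FALSE
Cyp3a41a	liver	0.08	0.89	-0.08	0.88	FALSE
Cyp3a16	liver	0.06	0.92	-0.10	0.85	FALSE
Slc35f2	liver	0.04	0.94	-0.16	0.76	FALSE
Tmed10	muscle	-0.30	0.56	-0.41	0.42	FALSE
Nlrc5	duodenum	0.90	0.02	0.78	0.07	TRUE
Tnk1	duodenum	-0.86	0.03	-0.84	0.03	TRUE
Wfs1	duodenum	0.81	0.05	0.83	0.04	TRUE
Gm5475	duodenum	-0.75	0.09	-0.88	0.02	TRUE
St6gal1	duodenum	-0.68	0.14	-0.46	0.36	FALSE
Pccb	duodenum	0.53	0.28	0.54	0.27	FALSE
Slc11a2	duodenum	-0.52	0.28	-0.73	0.10	TRUE
Wdr83	duodenum	0.51	0.30	0.47	0.34	FALSE
Lax1	duodenum	-0.49	0.32	-0.30	0.56	FALSE
Prkacb	duodenum	0.31	0.54	0.28	0.59	FALSE
Fyn	duodenum	0.27	0.60	0.17	0.75	FALSE
Stk3	duodenum	0.17	0.75	0.08	0.88	FALSE
Cyba	duodenum	0.15	0.78	-0.06	0.92	FALSE
Cyp4b1-ps2	duodenum	-0.14	0.79	-0.16	0.76	FALSE
Tbc1d31	duodenum	0.10	0.85	-0.15	0.77	FALSE
Ccdc146	ileum	-0.48	0.33	-0.37	0.47	FALSE
Tcf23	ileum	-0.30	0.56	-0.23	0.66	FALSE
1700016C15Rik	ileum	0.04	0.93	0.25	0.64	FALSE
Irf1	ileum	0.04	0.94	-0.10	0.85	FALSE
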