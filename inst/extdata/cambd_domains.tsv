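protein	domain_label	domain_string	r_1_10	r_1_12	r_1_14	r_1_16	r_1_5_10	notes
ABCA7	CaMBD1	1221LQALLLKRFLLARRSRRGLF1240	3	NA	1	NA	1	-
ABCA7	CaMBD2	1401QGLKTKKWVNEVRYGGFSLG1420	2	NA	NA	NA	1	-
CD33	CaMBD1	-	2	2	2	NA	NA	sequence-unavailable
CH3L1	CaMBD1	333SVKSKVQYLKDRQLAGAMVW352	1	1	1	1	NA	-
CLU	CaMBD1	33VAERLTRKYNELLKSYQWKM352	NA	2	1	NA	NA	coordinate-typo
CR1	CaMBD1	1090VVTYRCNLGSRGRKVFEL1107	NA	NA	NA	1	NA	-
EPHA1	CaMBD1	167NVERCSLGRLTRRGLYLA184	NA	1	1	1	NA	-
MS4A4E	CaMBD1	28HSYLCKGLQEKFFKRKPKV6	1	1	NA	NA	NA	coordinate-typo
MS4A4E	CaMBD2	107NYLKNLSWRIMGSYLCF123	NA	2	1	NA	1	-
MS4A6A	CaMBD1	101LSIATEKRLTKLLVH115	2	2	1	NA	NA	-
NLRP3	CaMBD1	564ENYGKFEKGYLIFVVRFLFGLVNQERT589	2	NA	1	1	NA	coordinate-typo
NLRP3	CaMBD2	603QIRLELLKWIEVKAKAKKLQIQ624	2	1	1	1	NA	-
PILRA	CaMBD1	208IMILGLICLLRWRRRKGQQRT229	1	NA	NA	NA	1	coordinate-typo
TREM2	CaMBD1	62RVVSTHNLWLLSFLRRWNG80	2	1	NA	1	NA	-
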