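category	gene_id	dmr_log2fc	dmr_p	deg_log2fc	deg_fdr	mirna_id	mirna_log2fc	mirna_fdr
red	Man2a1	1.224	0.002	-0.452	1.68933e-08	miR-92b-3p	0.421	0.002
red	Man2a1	1.224	0.002	-0.452	1.68933e-08	miR-191-5p	0.33	0.002
red	Man2a1	1.224	0.002	-0.452	1.68933e-08	miR-92a-3p	0.265	0.014
red	Atp6v0d1	1.548	0.038	-0.214	0.031	miR-125b-5p	0.266	0.015
blue	Camkk1	-2.714	2.23904e-06	0.42	0.047	miR-223-3p	-0.333	0.026
blue	Tnfaip8l1	-1.543	0.004	0.623	0.001	miR-223-3p	-0.333	0.026
blue	Suox	-1.929	0.004	0.353	0.048	miR-125b-1-3p	-0.36	0.031
blue	Rint1	-1.046	0.008	0.29	0.01	miR-223-3p	-0.333	0.026
blue	Pomk	-1.217	0.016	0.355	0.036	miR-223-3p	-0.333	0.026
blue	Thap2	-1.111	0.03	1.105	7.02311e-27	miR-223-3p	-0.333	0.026
blue	Zfp455	-1.154	0.034	0.575	0.023	miR-223-3p	-0.333	0.026
blue	Khdrbs3	-1.32	0.034	0.221	0.037	miR-223-3p	-0.333	0.026
blue	Arl3	-1.018	0.036	0.409	0	miR-223-3p	-0.333	0.026
green	Eml6	1.171	0.014	0.469	0.001	miR-223-3p	-0.333	0.026
green	Atp7b	1.294	0.017	0.806	0.005	miR-223-3p	-0.333	0.026
orange	Cul3	-1.59	0.003	-0.304	0.001	miR-92a-3p	0.265	0.014
orange	Stag2	-1.052	0.008	-0.347	0.001	miR-92a-3p	0.265	0.014
orange	Klf6	-1.083	0.018	-0.733	8.18305e-05	miR-92a-3p	0.265	0.014
orange	Klhl15	-1.493	0.02	-0.263	0.04	miR-92a-3p	0.265	0.014
orange	Chm	-1.067	0.021	-0.287	0.002	miR-92a-3p	0.265	0.014
orange	Atp11c	-1.082	0.045	-0.215	0.024	miR-125b-5p	0.266	0.015
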