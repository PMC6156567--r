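variant	kH	se_kH	KM_H	se_KM_H	eff	se_eff	Ea_H	se_Ea_H	Ea_D	se_Ea_D	delta_Ea	se_delta_Ea	lnA_H	se_lnA_H	lnA_D	se_lnA_D	A_ratio	se_A_ratio	kie	se_kie
B	3.25e-05	1e-06	NA	NA	NA	NA	14.5	0.8	16.7	0.7	2.3	1.1	13.7	1.4	16.0	1.1	0.107	0.01	4.6	0.1
R1	0.02	0.0008	0.96	0.06	24.5	1.8	10.8	1.1	15.1	1.0	4.3	1.5	14.0	1.8	19.6	1.7	0.004	0.0006	4.9	0.2
R4	0.96	0.09	1.10	0.17	877	159	5.6	0.8	9.8	0.8	4.2	1.2	9.1	1.3	14.4	1.4	0.005	0.0009	5.6	0.2
R5	1.43	0.06	0.53	0.05	2700	257	7.7	0.8	9.0	0.7	1.4	1.1	12.9	1.3	13.0	1.2	0.875	0.1211	8.6	0.2
R6	1.56	0.07	0.50	0.05	3100	332	9.5	0.5	11.7	0.5	2.2	0.7	16.1	0.8	17.8	0.8	0.181	0.0126	6.5	0.1
R7	2.51	0.14	0.58	0.07	4310	568	7.1	0.7	11.0	0.9	4.0	1.1	12.5	1.1	17.1	1.5	0.009	0.0011	7.0	0.2
R7-2	3.83	0.17	0.55	0.05	6970	669	6.9	0.4	11.3	0.5	4.4	0.6	12.7	0.7	18.1	0.8	0.005	0.0003	7.3	0.1
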