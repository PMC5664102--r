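pair_label	gene	symbol	betweenness	fdr	betweenness_ratio	minmax_score
bone--dentin	ENSP00000231572	RARS	122	<0.001	0.037	865
bone--dentin	ENSP00000230882	GHR	122	0.011	0.037	675
bone--dentin	ENSP00000313809	AMBN	122	0.012	0.037	583
bone--dentin	ENSP00000332353	PTCH1	155	0.033	0.047	878
bone--nerve	ENSP00000317272	MET	802	0.019	0.023	989
bone--nerve	ENSP00000419692	RXRA	459	0.026	0.013	964
bone--nerve	ENSP00000228682	GLI1	407	0.044	0.012	978
bone--vessel	ENSP00000295731	IHH	486	0.014	0.015	912
bone--vessel	ENSP00000317272	MET	634	0.018	0.02	984
bone--vessel	ENSP00000371067	JAK2	853	0.021	0.027	994
bone--vessel	ENSP00000419692	RXRA	353	0.026	0.011	964
dentin--nerve	ENSP00000360483	NDC1	280	0.004	0.037	466
dentin--nerve	ENSP00000313809	AMBN	280	0.012	0.037	819
dentin--nerve	ENSP00000231572	RARS	281	0.015	0.037	865
dentin--nerve	ENSP00000230882	GHR	281	0.04	0.037	675
dentin--vessel	ENSP00000231572	RARS	258	0.003	0.037	865
dentin--vessel	ENSP00000362649	HDAC1	112	0.01	0.016	993
dentin--vessel	ENSP00000262077	NUP153	251	0.024	0.036	456
dentin--vessel	ENSP00000387662	GCG	76	0.026	0.011	896
dentin--vessel	ENSP00000227507	CCND1	263	0.03	0.038	946
dentin--vessel	ENSP00000332973	SMAD3	490	0.038	0.07	875
dentin--vessel	ENSP00000332353	PTCH1	131	0.044	0.019	878
dentin--vessel	ENSP00000250003	MYOD1	208	0.048	0.0299	848
nerve--vessel	ENSP00000250003	MYOD1	2465	0.005	0.034	999
nerve--vessel	ENSP00000340944	PTPN11	1350	0.01	0.019	999
nerve--vessel	ENSP00000227507	CCND1	3568	0.022	0.049	991
nerve--vessel	ENSP00000371067	JAK2	2332	0.031	0.032	999
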