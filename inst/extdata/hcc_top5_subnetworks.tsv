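rank	gene	univariate_p	subnetwork_adjusted_p
1	CCR7	3.1e-01	8.69e-06
1	XCL1	5.1e-03	8.69e-06
1	VCAN	2.0e-02	8.69e-06
1	CCL21	4.8e-03	8.69e-06
1	CCL19	4.8e-03	8.69e-06
1	FBLN2	5.0e-04	8.69e-06
2	HIST1H2BJ	2.6e-01	1.02e-05
2	LOX	1.7e-01	1.02e-05
2	DPT	3.0e-02	1.02e-05
2	BAT3	5.3e-02	1.02e-05
2	ELN	4.7e-02	1.02e-05
2	FBLN2	5.0e-04	1.02e-05
2	ASS1	5.1e-02	1.02e-05
3	PPIL2	2.3e-01	1.61e-05
3	BSG	1.9e-01	1.61e-05
3	MMP1	2.0e-04	1.61e-05
3	SLC16A1	6.0e-02	1.61e-05
3	TIMP1	1.5e-01	1.61e-05
3	CAV1	1.3e-01	1.61e-05
3	TNFRSF1B	2.7e-03	1.61e-05
3	CSNK2A2	3.5e-02	1.61e-05
3	GNAI2	3.2e-02	1.61e-05
3	MAPK3	3.3e-02	1.61e-05
4	CCR6	4.5e-01	4.59e-05
4	CCL20	2.1e-01	4.59e-05
4	VCAN	2.0e-02	4.59e-05
4	FBLN2	4.0e-04	4.59e-05
4	CCL21	4.8e-03	4.59e-05
4	XCL1	5.1e-03	4.59e-05
5	ACAA2	2.6e-02	9.65e-05
5	SCP2	1.3e-01	9.65e-05
5	ACOX1	8.2e-01	9.65e-05
5	CAV1	1.3e-01	9.65e-05
5	TNFRSF1B	2.7e-03	9.65e-05
5	CSNK2A2	3.5e-02	9.65e-05
5	GNAI2	3.2e-02	9.65e-05
5	MAPK3	3.3e-02	9.65e-05
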