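network	condition	term	estimate	se	t	p	p_fdr
VN	rest	binocular_cs	-0.0012	0.0029	-0.4105	0.6815	0.9805
VN	task	binocular_cs	0.0067	0.0022	2.9911	0.0028	0.0148
DMN	rest	binocular_cs	0.0002	0.0027	0.0688	0.9452	0.9805
DMN	task	binocular_cs	0.0081	0.0026	3.1532	0.0016	0.0129
SMN	rest	binocular_cs	0.0072	0.0022	3.3426	0.0008	0.0129
SMN	task	binocular_cs	-0.0002	0.0018	-0.0999	0.9204	0.9805
BGN	rest	binocular_cs	NA	0.0020	0.0325	0.9741	0.9805
BGN	task	binocular_cs	-0.0002	0.0021	-0.1133	0.9098	0.9805
CEN	rest	binocular_cs	-0.0001	0.0022	-0.0675	0.9462	0.9805
CEN	task	binocular_cs	-0.0005	0.0019	-0.2595	0.7953	0.9805
DAN	rest	binocular_cs	0.0026	0.0024	1.0753	0.2823	0.7721
DAN	task	binocular_cs	0.0032	0.0021	1.5118	0.1306	0.5224
FTN	rest	binocular_cs	-0.0002	0.0019	-0.1088	0.9134	0.9805
FTN	task	binocular_cs	-0.0012	0.0016	-0.7326	0.4638	0.9805
SN	rest	binocular_cs	0.0021	0.0020	1.0592	0.2895	0.7721
SN	task	binocular_cs	NA	0.0014	0.0245	0.9805	0.9805
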