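r01	g001	1
r02	g001	1
r03	g001	0
r04	g001	0
r05	g001	0
r01	g002	0
r02	g002	0
r03	g002	0
r04	g002	0
r05	g002	0
r01	g003	1
r02	g003	0
r03	g003	1
r04	g003	0
r05	g003	0
r01	g004	1
r02	g004	1
r03	g004	0
r04	g004	0
r05	g004	0
r01	g005	0
r02	g005	0
r03	g005	1
r04	g005	1
r05	g005	0
r01	g006	0
r02	g006	0
r03	g006	1
r04	g006	0
r05	g006	0
r01	g007	0
r02	g007	1
r03	g007	0
r04	g007	0
r05	g007	0
r01	g008	0
r02	g008	1
r03	g008	0
r04	g008	1
r05	g008	0
r01	g009	0
r02	g009	1
r03	g009	0
r04	g009	1
r05	g009	0
r01	g010	1
r02	g010	1
r03	g010	0
r04	g010	1
r05	g010	0
r01	g011	0
r02	g011	0
r03	g011	0
r04	g011	0
r05	g011	0
r01	g012	0
r02	g012	0
r03	g012	0
r04	g012	0
r05	g012	0
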