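gene	tissue1_s001	tissue1_s002	tissue1_s003	tissue1_s004	tissue1_s005	tissue1_s006	tissue1_s007	tissue1_s008
g001	-0.64403668338064191	3.7409824023014719	0.42899787729303379	6.3228158858224202	-2.204186788983896	-0.090213619332313769	-4.4761681147943415	2.4795169883900408
g002	-2.1811273356922545	5.2010381531073264	-0.44708634998477165	6.7460395440177887	-1.6711908101466502	0.065805429033422722	-5.0223309336689672	2.8208368145089251
g003	-1.0924904449834476	4.6604250412674615	-1.5481803990959122	6.1195926235631326	-1.4114612014627026	-0.021478729402592579	-4.5481337217106965	3.3273073089779137
g004	-0.14133669496522416	6.1584093905657973	-0.23887972558386777	5.5484752014891745	-1.3046849832715808	0.58335213231969951	-3.0425702469357008	2.276392352073771
g005	-1.5106209945117803	5.5633784518632616	-0.84189336054999986	7.1162670076790615	-1.8797694564945358	0.81976098772587158	-4.6079861159490294	0.095927085027514458
g006	2.4946083325799204	0.066260675232375554	-0.32084420481346299	-0.44914255931669028	-0.26568509213183006	0.012047132611793021	0.76543322408819381	-2.8501385647838027
g007	3.1584755455243037	1.9203973077953465	2.1999101339218714	-0.94872480376559853	-1.7468371412387578	-0.089074995965237491	2.1739241277202797	-0.90634219838955832
g008	2.7116370135517993	0.99678100049120244	0.91223325579107484	0.51382679600268999	-2.5931400676732026	1.4010345952539609	2.770061646614753	-0.4134992726861253
g009	2.0858613695209085	1.5587186069615038	0.3375014727839159	-0.84304847170081809	-1.0148185377808985	0.16703474331959733	1.9457159618323696	-2.0068682446586781
g010	0.86590434276980188	2.4520092398476878	2.1310896151870891	0.49407471190384605	-0.49257478040980046	1.8102070297092894	1.3623828339861421	-1.6147117570496152
g011	1.8037597538502814	-0.36330323440106843	-1.1589618719151598	0.38809936130469663	-1.0056317857947084	0.9258634764712963	-1.1175816150898985	-0.63355871482196413
g012	-0.9668728823813949	-0.010094030409008335	-0.040609333633441533	-0.24340044967878238	1.0456028922160887	0.59867955441912524	-1.9928760908180891	-0.37442315378029661
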