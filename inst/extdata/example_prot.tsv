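sample_id	prot_f0001	prot_f0002	prot_f0003	prot_f0004	prot_f0005	prot_f0006	prot_f0007	prot_f0008
s0001	0.213240068110922	2.61676986001161	0.287515465960351	-1.42603337961283	-0.4041879962217	3.19588668290907	-0.220173783581705	-3.09547032572666
s0002	-0.745323025086465	0.910476287684425	1.84690466704001	-0.682555455242883	-3.1285408028031	1.83433027712774	1.71639059917912	-1.6590305900392
s0003	0.00641918255780611	-0.0462970604773553	-0.101332376068742	0.335536911941299	-0.00466824679842354	0.159694612440657	-0.0552736660672858	-0.136518096057247
s0004	0.101996284459516	2.09160090986761	-0.569586695712231	-1.18848994803494	0.757006449312691	2.57316164859178	-0.671841804600547	-2.55092962132135
s0005	0.200241628793043	1.46146666186399	-0.18149008209231	-0.699610157409243	0.16956946089535	1.88219623421248	-0.399817898009184	-1.57775765703272
s0006	-0.174092200215566	1.69416736277668	1.06426236964306	-1.14229137048737	-1.88127648792835	2.55620660960328	0.892325856908321	-2.49726307041553
s0007	0.669107063649992	4.08554827012045	-1.36869894451887	-1.94885226493661	2.4324175526504	4.6090844572249	-2.0705160735419	-4.90129887404511
s0008	0.0218757895119309	2.45691911678821	-0.072886813459904	-1.38098088699781	-0.193537471986265	3.17993748028318	-0.146359581302276	-2.9555375114964
s0009	-0.556213005289738	2.27972357808498	1.47782584059693	-1.26020342364692	-2.68790304509425	2.94318524259455	1.25676418866635	-3.01879819178368
s0010	-1.51760718664283	1.52766245888006	3.65267870809771	-1.04413570769656	-6.7410158007075	2.74787811735888	3.40492228860124	-2.33114668442979
s0011	0.202738179467365	0.385149823394528	-0.779772664794957	-0.353013592440608	1.57301052434904	0.551528401399206	-0.879671944968324	-0.482594750365688
s0012	-0.199453806025328	0.844671496849062	0.686485903743001	-0.457923801595335	-1.15266071332606	1.13482030399678	0.694275873247736	-1.13548764618035
s0013	0.0121267022676218	-1.61973447652438	-0.623118045231863	0.980530715841075	1.19226312286119	-2.28088590228457	-0.339702903890237	2.01805257845679
s0014	0.730455337090169	-1.63114102366228	-2.01679528000094	0.967621159257636	3.48226026611942	-2.12651921659094	-1.54429891771624	1.99770422037829
s0015	0.643586096333491	-2.84534492342567	-1.75714901183449	1.34163936249322	3.05357748091756	-3.5364813455821	-1.59265943814663	3.47813298625836
s0016	0.443144479500135	-2.52842382324587	-1.4352586381403	1.3576369460196	2.73402618339497	-3.51139461563759	-1.22395421970084	3.26137752137952
s0017	0.842961760625185	-0.870994749406072	-1.64643496720252	0.617782887137606	3.41319511879217	-1.57931523031352	-1.93246248519736	1.11578893280167
s0018	0.67282470118562	-0.601492927109058	-1.45040058113546	0.378726998068699	3.02587190535816	-1.22332262568818	-1.59163659744899	0.993066717988404
s0019	0.110601920931751	-2.26194870492235	-0.711864782386961	1.00018176946183	1.51231550073545	-3.12396976272889	-0.26448536117782	2.77139026638113
s0020	-0.997632474998599	-3.15593516885184	2.03343653772812	1.4666892040271	-3.76674221755397	-3.66305303690391	2.68647785227555	3.69071172692547
s0021	0.488982903408027	-1.65775238328595	-1.65228103181229	0.814390100855629	2.70773095700194	-2.42476440862829	-1.22144099188172	2.30020463443973
s0022	0.23443394011102	-3.08645370114069	-0.449280273934804	1.62302114552712	1.15948073488541	-3.94357054422882	-0.0557407103756705	3.80468181370863
s0023	0.0363432557764704	-2.53373124011038	-0.488406178783848	1.23880743313154	0.845986905775664	-3.04414916897245	-0.111301831968465	3.0067804450734
s0024	-0.562253213032613	-1.18484381082782	1.61520672619515	0.605357191473247	-2.4603728072417	-1.36424678635745	1.58397703334483	1.43361665649588
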