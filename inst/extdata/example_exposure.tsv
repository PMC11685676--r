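variant_id	chromosome	base_pair_location	effect_allele	other_allele	effect_allele_frequency	beta	standard_error	p_value	n
rsx0001	1	100000	C	A	0.25204054155619815	7.965743599183285e-4	0.005150042000275012	0.8770788237284712	100000
rsx0002	1	200000	G	A	0.49068133333930747	0.005685649280608154	0.004472912856042273	0.20368275717307335	100000
rsx0003	1	300000	C	A	0.06744146205019207	-0.012895905890517943	0.008916275159986668	0.14808373327987712	100000
rsx0004	1	400000	T	C	0.09786299570696429	0.023999831625571375	0.007525571747053927	0.0014271448000245438	100000
rsx0005	1	500000	T	G	0.30772393255028874	0.023160119524549407	0.004844675648045887	1.7483326200264927e-6	100000
rsx0006	1	600000	A	C	0.2760308767552488	0.035517860827455214	0.005002028335664201	1.2413406289136e-12	100000
rsx0007	1	700000	T	C	0.19804678969085215	0.045189305633747096	0.005610823193468339	8.0162088131679e-16	100000
rsx0008	1	800000	C	A	0.08847351862350479	-0.008938005905468333	0.007873969120159799	0.2563193989524654	100000
rsx0009	1	900000	A	G	0.06576017601182685	0.039204149116235834	0.009021408126452744	1.3884512256230646e-5	100000
rsx0010	1	1000000	A	C	0.4748910472262651	0.03914436706881993	0.0044777856442292105	2.2921656512599046e-18	100000
rsx0011	1	1100000	A	C	0.4342900024028495	0.006973440724783916	0.004511263132355986	0.12215661631737071	100000
rsx0012	1	1200000	G	A	0.22384956413879992	0.026201931729915952	0.00536455772392977	1.038143739051966e-6	100000
rsx0013	1	1300000	G	A	0.48476527114398776	0.013867400559006014	0.004474213339925122	0.001939095535510762	100000
rsx0014	1	1400000	C	A	0.19722597663057967	-3.983086042162903e-4	0.005619611454771064	0.9434946001941472	100000
rsx0015	1	1500000	G	T	0.08387825367972254	0.0688073404569594	0.00806647358600633	1.4629741918363755e-17	100000
rsx0016	1	1600000	T	C	0.36350318904733286	0.06747137949547975	0.004648713414668451	9.880240427338244e-48	100000
rsx0017	1	1700000	T	G	0.18539841911988336	0.03776147626771414	0.005753860979315988	5.280435029752483e-11	100000
rsx0018	1	1800000	C	T	0.33888323220890015	0.02607008528847937	0.004724119509158039	3.418923873268797e-8	100000
rsx0019	1	1900000	T	G	0.10913183147786185	0.04702400188076013	0.0071713770918083964	5.483524977669048e-11	100000
rsx0020	1	2000000	T	G	0.4069791782530956	0.013077261863347083	0.0045515983964875524	0.00406447199579936	100000
rsx0021	1	2100000	T	G	0.07473804947221652	0.03974263251016273	0.008503187800187313	2.9560387555403636e-6	100000
rsx0022	1	2200000	T	C	0.4634610540699214	0.009432984980795842	0.004484125446600013	0.03540987505960918	100000
rsx0023	1	2300000	A	G	0.07286341073922814	0.03948435646496404	0.008603167795454574	4.442798389924859e-6	100000
rsx0024	1	2400000	T	G	0.44772168833296744	0.01028957907017882	0.004496783114538737	0.02212535962531451	100000
rsx0025	1	2500000	A	C	0.12618254952831193	0.009535700541624975	0.00673402921751811	0.15676180187301156	100000
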