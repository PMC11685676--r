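variant_id	chromosome	base_pair_location	effect_allele	other_allele	effect_allele_frequency	beta	standard_error	p_value	n
rsx0001	1	100000	C	A	0.25204054155619815	0.0019720277074360163	0.005150042000275012	0.7017828790894913	100000
rsx0002	1	200000	G	A	0.49068133333930747	0.007575856943651635	0.004472912856042273	0.09031871546721472	100000
rsx0003	1	300000	C	A	0.06744146205019207	-0.0025093010446235447	0.008916275159986668	0.7783811504875258	100000
rsx0004	1	400000	T	C	0.09786299570696429	0.008068206187630593	0.007525571747053927	0.28367268894726455	100000
rsx0005	1	500000	T	G	0.30772393255028874	0.005128663083701892	0.004844675648045887	0.28977357541720045	100000
rsx0006	1	600000	A	C	0.2760308767552488	0.009348294974411902	0.005002028335664201	0.061636610989753905	100000
rsx0007	1	700000	T	C	0.19804678969085215	0.010730347180745285	0.005610823193468339	0.05582013621516199	100000
rsx0008	1	800000	C	A	0.08847351862350479	-0.0054264620905393815	0.007873969120159799	0.49071958634320484	100000
rsx0009	1	900000	A	G	0.06576017601182685	0.011818776703095644	0.009021408126452744	0.19016838564871236	100000
rsx0010	1	1000000	A	C	0.4748910472262651	0.0066826919751354725	0.0044777856442292105	0.13559170083329108	100000
rsx0011	1	1100000	A	C	0.4342900024028495	0.0069191317515732665	0.004511263132355986	0.12509215413492927	100000
rsx0012	1	1200000	G	A	0.22384956413879992	-0.00993066275558352	0.00536455772392977	0.0641463217848749	100000
rsx0013	1	1300000	G	A	0.48476527114398776	0.0051162535946930945	0.004474213339925122	0.25283192275113964	100000
rsx0014	1	1400000	C	A	0.19722597663057967	9.290928548289461e-5	0.005619611454771064	0.9868091400976946	100000
rsx0015	1	1500000	G	T	0.08387825367972254	0.0025802802292555754	0.00806647358600633	0.7490614932637881	100000
rsx0016	1	1600000	T	C	0.36350318904733286	0.009731501362151868	0.004648713414668451	0.036315674703412265	100000
rsx0017	1	1700000	T	G	0.18539841911988336	0.006120703885065589	0.005753860979315988	0.28743926859268276	100000
rsx0018	1	1800000	C	T	0.33888323220890015	0.0030091108459729078	0.004724119509158039	0.5241459785566182	100000
rsx0019	1	1900000	T	G	0.10913183147786185	0.012437379587097834	0.0071713770918083964	0.08286337643695106	100000
rsx0020	1	2000000	T	G	0.4069791782530956	0.0048689619362668225	0.0045515983964875524	0.2847427793326775	100000
rsx0021	1	2100000	T	G	0.07473804947221652	0.008396398119047509	0.008503187800187313	0.3234263863231904	100000
rsx0022	1	2200000	T	C	0.4634610540699214	0.005317584152683241	0.004484125446600013	0.23567414344501075	100000
rsx0023	1	2300000	A	G	0.07286341073922814	0.01962624983126075	0.008603167795454574	0.022531778928325984	100000
rsx0024	1	2400000	T	G	0.44772168833296744	0.008912674767764148	0.004496783114538737	0.047477980397015715	100000
rsx0025	1	2500000	A	C	0.12618254952831193	-0.006694144356524146	0.00673402921751811	0.32018532441238873	100000
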