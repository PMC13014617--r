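disease	metabolite	score	p_value	fdr	pmid
Alzheimer disease	3-Hydroxybutyric acid	-0.02668	0.0434	0.08228	33803253
Anemia, sickle cell	Butyrate	-0.0851	0.04993	0.0924	26719803
Anorexia	Butyrate	-0.06997	0.00564	0.01562	36675302
Autistic disorder	Cysteine	-0.20618	0.00117	0.00431	34658941
Autoimmune diseases	Phenylalanine	-0.1158	0.00004	0.00027	34523675
Autoimmune diseases	Nicotinic acid	-0.11209	0.00001	0.00005	37845835
Bipolar disorder	Leucine	-0.14976	0.00012	0.00065	27179557
Bipolar disorder	Phenylalanine	-0.14853	0.00006	0.00037	3944066
Bipolar disorder	l-Isoleucine	-0.14124	0.00012	0.00067	27179557
Cardiovascular diseases	Pantothenic acid	-0.09165	0.02316	0.04985	38949913
Cardiovascular diseases	Tryptophan	-0.08984	0.02381	0.05079	28179491
Cardiovascular diseases	Nicotinamide	-0.08817	0.02988	0.06073	33568522
Colonic diseases	Succinic acid	-0.21583	0.0002	0.00102	24856584
Colonic diseases	Arginine	-0.21234	0.00029	0.00141	doi: 10.1016/j.jff.2018.11.019
Colonic diseases	Lysine	-0.20924	0.00038	0.00177	38351003
Colonic diseases	Alanine	-0.20911	0.0004	0.00181	37898769
Colonic diseases	Valine	-0.20756	0.0004	0.00183	9468343
Cystic fibrosis	Stearic acid	-0.15414	0.0032	0.00982	33025706
Cystic fibrosis	Aspartic acid	-0.15413	0.00346	0.01047	32974221
Diabetes mellitus	Indole	-0.05788	0.00007	0.00043	34192642
Diabetes mellitus, type 2	Taurocholic acid	-0.04509	0.01971	0.04402	30298865
Diabetes, gestational	Daidzein	-0.005	0.01754	0.04	32506178
Diabetes, gestational	Genistein	-0.00238	0.00088	0.00346	32506178
Diabetes, gestational	Glycitein	-0.00238	0.00088	0.00346	32506178
Diarrhea	Alanine	-0.1475	0.00006	0.00035	2007961
Diarrhea	Tryptophan	-0.14226	0.00003	0.00023	38877403
Diarrhea	Nicotinic acid	-0.14183	0.00003	0.0002	207728
Gastroesophageal reflux	Arginine	-0.14756	0.00178	0.00606	22207112
Gastroesophageal reflux	Glycine	-0.1459	0.00116	0.0043	22207112
Gingivitis	D-Arabinose	-0.00281	0.04324	0.08207	35866308
Graves disease	Melatonin	-0.06502	2.68E-07	4.3e-06	27374868
HIV	Spermidine	-0.27103	3.73E-08	8.06e-07	37406129
Hematologic neoplasms	Arginine	-0.28095	9.18E-10	4.04e-08	27745970
Hypertension	Lactulose	-0.02006	0.04882	0.09066	30825362
Irritable bowel syndrome	Chenodeoxycholic acid	-0.02308	0.04046	0.07768	28666948
Liver cirrhosis	Daidzein	-0.01555	1.87E-06	0.00002	37780202
Liver cirrhosis	Cholecalciferol	-0.00699	0.02147	0.04684	30271082
Liver diseases	Taurocholic acid	-0.03012	0.03481	0.06891	35199809
Liver diseases	Dextrin	-0.02768	0.00013	0.00072	21936050
Lung diseases	Nicotinic acid	-0.0866	0.00231	0.00748	22375599
Lung diseases	Inosine	-0.0844	0.00403	0.0118	36313960
Metabolic syndrome	Spermine	-0.08449	0.00017	0.00088	24530553
Metabolic syndrome	Linolenic Acid	-0.0819	0.00003	0.00021	22894911
Migraine disorders	Nicotinic acid	-0.10174	0.00002	0.00017	12934790
Stomach neoplasms	Oleic Acid	-0.28251	1.21E-08	3.15e-07	24823908
Stomach neoplasms	Alanine	-0.27636	7.68E-08	1.5e-06	25622826
Stomach neoplasms	Arginine	-0.27426	9.25E-08	1.76e-06	19036482
Thyroid diseases	Leucine	-0.17368	0.00001	9.87e-05	30524299
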