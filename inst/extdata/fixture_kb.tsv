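name	chrom	start	end	expected_dosage	evidence	mechanism	syndrome	genes
1p36_deletion	1	3454000	6454000	loss	established_multi_report	FALSE	TRUE	
1q21.1_microduplication	1	13070600	14371400	gain	established_multi_report	FALSE	TRUE	
2q37_microdeletion	2	1524100	4448900	loss	established_multi_report	FALSE	TRUE	
Wolf-Hirschhorn	4	2434000	5434000	loss	established_multi_report	FALSE	TRUE	
Cri-du-chat	5	7788000	10788000	loss	established_multi_report	FALSE	TRUE	
5q_trisomy	5	27700000	30700000	gain	established_multi_report	FALSE	TRUE	
Sotos	5	41015100	42543900	loss	established_multi_report	FALSE	TRUE	
Silver-Russell_UPD7	7	1500000	3000000	upd_maternal	established_multi_report	FALSE	TRUE	
Williams-Beuren	7	4215400	5354600	loss	established_multi_report	FALSE	TRUE	ELN
Waardenburg_8p23	8	4452500	7452500	loss	established_multi_report	FALSE	TRUE	
Branchio-Otorenal	8	18409500	21409500	loss	established_multi_report	FALSE	TRUE	
9p_partial_monosomy	9	83743500	86743500	loss	established_multi_report	FALSE	TRUE	
9p_partial_trisomy	9	5000000	15000000	gain	established_multi_report	FALSE	TRUE	
10p_partial_deletion	10	5024500	8024500	loss	established_multi_report	FALSE	TRUE	
10p15.3_deletion	10	16396200	19173800	loss	established_multi_report	FALSE	TRUE	
Distal_trisomy_10q	10	39990000	42990000	gain	established_multi_report	FALSE	TRUE	
10qter_deletion	10	64779000	67779000	loss	established_multi_report	FALSE	TRUE	
15q11q13_deletion_PWS_AS	15	24000000	28800000	loss	established_multi_report	FALSE	TRUE	SNRPN,UBE3A
Prader-Willi_UPD15	15	24000000	26000000	upd_maternal	established_multi_report	FALSE	TRUE	
Angelman_UPD15	15	24000000	26000000	upd_paternal	established_multi_report	FALSE	TRUE	
15q11q13_duplication	15	24000000	28800000	gain	established_multi_report	FALSE	TRUE	
15q13.3_duplication	15	31200000	31900000	gain	established_multi_report	FALSE	TRUE	
15q26_deletion	15	40313400	42820600	loss	established_multi_report	FALSE	TRUE	
16p11.2_microduplication	16	1178600	1647400	gain	established_multi_report	FALSE	TRUE	
16_partial_trisomy	16	14160000	17160000	gain	established_multi_report	FALSE	TRUE	
17_partial_trisomy	17	2350500	5350500	gain	established_multi_report	FALSE	TRUE	
18q_deletion	18	38754700	41188300	loss	established_multi_report	FALSE	TRUE	
18q_duplication	18	120414500	123414500	gain	established_multi_report	FALSE	TRUE	
22q11.2_duplication_proximal	22	17500000	19300000	gain	established_multi_report	FALSE	TRUE	
22q11.2_duplication_distal	22	20000000	21000000	gain	established_multi_report	FALSE	TRUE	
22q11.2_deletion	22	17500000	19300000	loss	established_multi_report	FALSE	TRUE	TBX1
MECP2_duplication	X	153200000	153500000	gain	established_multi_report	FALSE	TRUE	MECP2
Temple_UPD14	14	42887000	45887000	upd_maternal	established_multi_report	FALSE	TRUE	
AUTS2_syndrome	7	9653000	10317000	loss	established_multi_report	FALSE	TRUE	AUTS2
Kleefstra	9	94567100	95207900	loss	established_multi_report	FALSE	TRUE	EHMT1
15q24_microdeletion	15	47392100	49456900	loss	established_multi_report	FALSE	TRUE	
1q25.1q31.1_del	1	23180000	26180000	loss	established_multi_report	FALSE	FALSE	
2p16.1p12_del	2	15805000	18805000	loss	established_multi_report	FALSE	FALSE	
2p21p13.2_dup	2	42417000	45417000	gain	established_multi_report	FALSE	FALSE	
2p25.3p25.2_dup	2	63969000	66969000	gain	established_multi_report	FALSE	FALSE	
3p14.1p11.1_dup	3	10288500	13288500	gain	established_multi_report	FALSE	FALSE	
4p16.3p16.1_dup	4	14094000	17094000	gain	established_multi_report	FALSE	FALSE	
4p16.3_del	4	24439500	25395500	loss	established_multi_report	FALSE	FALSE	
4q31.3q35.2_dup	4	47308500	50308500	gain	established_multi_report	FALSE	FALSE	
4q34.14q35.2_dup	4	80050500	83050500	gain	established_multi_report	FALSE	FALSE	
6q23.3q24.2_del	6	3202500	6202500	loss	established_multi_report	FALSE	FALSE	
8p23.3p22_del	8	36064000	39064000	loss	established_multi_report	FALSE	FALSE	
13q21.1q32.2_del	13	19036500	22036500	loss	established_multi_report	FALSE	FALSE	
14q11.2q21.2_dup	14	102071500	105071500	gain	established_multi_report	FALSE	FALSE	
14q32.12p32.33_dup	14	123677000	126677000	gain	established_multi_report	FALSE	FALSE	
15q26.2q26.3_del	15	54015600	56420400	loss	established_multi_report	FALSE	TRUE	
16q24.2q24.3_dup	16	29761100	31897900	gain	established_multi_report	FALSE	FALSE	
18p11.32p11.31_del	18	166379500	169379500	loss	established_multi_report	FALSE	TRUE	
18p11.32p11.21_del	18	180197500	183197500	loss	established_multi_report	FALSE	FALSE	
18q21.32q23_dup	18	200730000	203730000	gain	established_multi_report	FALSE	TRUE	
19p13.3p13.2_dup	19	3163500	6163500	gain	established_multi_report	FALSE	FALSE	
20p13p12.3_del	20	4422000	7422000	loss	established_multi_report	FALSE	FALSE	
21q22.11q22.3_del	21	6027500	9027500	loss	established_multi_report	FALSE	FALSE	
22q13.31q13.33_dup	22	26324000	29324000	gain	established_multi_report	FALSE	FALSE	
Xq22.3q27.1_dup	X	15662000	18662000	gain	established_multi_report	FALSE	FALSE	
CADM2_3p12.2p11.1_del	3	29286000	32286000	loss	single_report	FALSE	FALSE	CADM2,CHMP2B,POU1F1,CGGBP1
2q13_del	2	72914400	74301600	loss	single_report	FALSE	FALSE	
7q11.22q21.11_del	7	21894000	24894000	loss	single_report	FALSE	FALSE	
19p13.2_del	19	12553000	14361000	loss	single_report	FALSE	FALSE	
20p13_del	20	14941800	15724200	loss	single_report	FALSE	FALSE	
CTNNA2	2	78973500	79173500	either	candidate_gene	FALSE	FALSE	CTNNA2
DPP10	2	83686100	83798900	either	candidate_gene	FALSE	FALSE	DPP10
CNTNAP5	2	87951500	88151500	either	candidate_gene	FALSE	FALSE	CNTNAP5
TRIP12	2	92301500	92393500	either	candidate_gene	FALSE	FALSE	TRIP12
GRM7	3	39482000	39682000	either	candidate_gene	FALSE	FALSE	GRM7
RSRC1	3	44286500	44486500	either	candidate_gene	FALSE	FALSE	RSRC1
PIGG	4	95014900	95142100	either	candidate_gene	FALSE	FALSE	PIGG
ARHGEF38	4	99174200	99303800	either	candidate_gene	FALSE	FALSE	ARHGEF38
KHDRBS2	6	12654500	12854500	either	candidate_gene	FALSE	FALSE	KHDRBS2
AHI1	6	17114300	17196700	either	candidate_gene	FALSE	FALSE	AHI1
PARK2	6	21263600	21324400	either	candidate_gene	FALSE	FALSE	PARK2
SDK1	7	36399900	36495100	either	candidate_gene	FALSE	FALSE	SDK1
GRM8	7	40512600	40557400	either	candidate_gene	FALSE	FALSE	GRM8
CTNNA3	10	73106400	73165600	either	candidate_gene	FALSE	FALSE	CTNNA3
LRRC4C	11	1020800	1187200	either	candidate_gene	FALSE	FALSE	LRRC4C
APBA2	15	61478500	61678500	either	candidate_gene	FALSE	FALSE	APBA2
CHRNA7	15	66553500	66753500	either	candidate_gene	FALSE	FALSE	CHRNA7
RBFOX1	16	36212000	36412000	either	candidate_gene	FALSE	FALSE	RBFOX1
GRIN2A	16	40585000	40785000	either	candidate_gene	FALSE	FALSE	GRIN2A
LAMA1	18	216096500	216296500	either	candidate_gene	FALSE	FALSE	LAMA1
MIB1	18	220467200	220564800	either	candidate_gene	FALSE	FALSE	MIB1
PTPRT	20	19829700	19891300	either	candidate_gene	FALSE	FALSE	PTPRT
AIFM3	22	34754000	34954000	either	candidate_gene	FALSE	FALSE	AIFM3
IGBP1	X	37424500	37624500	either	candidate_gene	FALSE	FALSE	IGBP1
SMS	X	41742500	41882500	either	candidate_gene	FALSE	FALSE	SMS
16p13.11_microduplication	16	45525500	45725500	gain	candidate_gene	FALSE	FALSE	
4p16.2p16.1_dup_VUS	4	103466500	103666500	gain	candidate_gene	FALSE	FALSE	
21q22.3_dup_VUS	21	19384000	19584000	gain	candidate_gene	FALSE	FALSE	
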