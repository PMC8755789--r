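subject_id	chrom	start	end	type	copy_state	marker_count	parent_of_origin
D063_M	1	12908000	14533999	duplication	3	813	
D064_F	15	23770500	29029499	deletion	1	2629	
D032_F	15	23269500	29530499	deletion	1	3130	
D069_M	15	23780500	29019499	deletion	1	2619	
D060_M	16	44911000	46339999	duplication	3	714	
D027_M	X	153161500	153538499	duplication	3	188	
D070_F	X	153138000	153561999	duplication	2	212	
A264_M	X	153146000	153553999	duplication	3	204	
A286_F	2	78475000	79671999	duplication	3	598	
A269_F	2	83672000	83812999	duplication	3	70	
A270_M	2	87813000	88289999	duplication	3	238	
A265_M	2	92290000	92404999	duplication	3	57	
A268_M	3	38995000	40168999	deletion	1	587	
A271_F	3	44169000	44603999	deletion	1	217	
A272_F	4	94999000	95157999	deletion	1	79	
A273_F	4	99158000	99319999	duplication	3	81	
A266_F	6	12405000	13103999	duplication	3	349	
A274_F	6	17104000	17206999	duplication	3	51	
A266_F	6	21256000	21331999	deletion	1	38	
A275_F	6	21207000	21380999	deletion	1	87	
A277_F	7	40507000	40562999	duplication	3	28	
A265_M	10	73099000	73172999	deletion	1	37	
A278_F	11	1000000	1207999	duplication	3	104	
A279_F	15	60721000	62435999	duplication	3	857	
A280_F	15	66436000	66870999	duplication	3	217	
A281_F	16	36165000	36458999	deletion	1	147	
A282_F	16	40459000	40910999	duplication	3	226	
A287_M	18	220455000	220576999	deletion	1	61	
A288_M	20	19822000	19898999	deletion	1	38	
A289_F	22	34648000	35059999	duplication	3	206	
A284_M	X	37324000	37724999	duplication	3	200	
A285_M	X	41725000	41899999	duplication	3	87	
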