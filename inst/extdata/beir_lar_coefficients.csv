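kind,sex,site,age0,age5,age10,age15,age20,age30,age40,age50,age60,age70,age80
incidence,male,stomach,76,65,55,46,40,28,27,25,20,14,7
incidence,male,colon,336,285,241,204,173,125,122,113,94,65,30
incidence,male,liver,61,50,43,36,30,22,21,19,14,8,3
incidence,male,lung,314,261,216,180,149,105,104,101,89,65,34
incidence,male,prostate,93,80,67,57,48,35,35,33,26,14,5
incidence,male,bladder,209,177,150,127,108,79,79,76,66,47,23
incidence,male,other,1123,672,503,394,312,198,172,140,98,57,23
incidence,male,thyroid,115,76,50,33,21,9,3,1,0.3,0.1,0
incidence,male,all_solid,2326,1667,1325,1076,881,602,564,507,407,270,126
incidence,male,leukemia,237,149,120,105,96,84,84,84,82,73,48
incidence,male,all_cancers,2563,1816,1445,1182,977,686,648,591,489,343,174
incidence,female,stomach,101,85,72,61,52,36,35,32,27,19,11
incidence,female,colon,220,187,158,134,114,82,79,73,62,45,23
incidence,female,liver,28,23,20,16,14,10,10,9,7,5,2
incidence,female,lung,733,608,504,417,346,242,240,230,201,147,77
incidence,female,breast,1171,914,712,553,429,253,141,70,31,12,4
incidence,female,uterus,50,42,36,30,26,18,16,13,9,5,2
incidence,female,ovary,104,87,73,60,50,34,31,25,18,11,5
incidence,female,bladder,212,180,152,129,109,79,78,74,64,47,24
incidence,female,other,1339,719,523,409,323,207,181,148,109,68,30
incidence,female,thyroid,634,419,275,178,113,41,14,4,1,0.3,0
incidence,female,all_solid,4592,3265,2525,1988,1575,1002,824,678,529,358,177
incidence,female,leukemia,185,112,86,76,71,63,62,62,57,51,37
incidence,female,all_cancers,4777,3377,2611,2064,1646,1065,886,740,586,409,214
mortality,male,stomach,41,34,30,25,21,16,15,15,13,11,7
mortality,male,colon,163,139,117,99,84,61,60,57,49,36,21
mortality,male,liver,44,37,31,27,23,16,16,14,12,8,4
mortality,male,lung,318,264,219,182,151,107,107,104,93,71,42
mortality,male,prostate,17,15,12,10,9,6,7,7,7,7,5
mortality,male,bladder,45,38,32,27,23,17,17,17,16,13,8
mortality,male,other,400,255,200,162,134,94,88,77,58,36,17
mortality,male,all_solid,1028,781,641,533,444,317,310,289,246,181,102
mortality,male,leukemia,71,71,71,70,67,64,67,71,73,69,51
mortality,male,all_cancers,1099,852,712,603,511,381,377,360,319,250,153
mortality,female,stomach,57,48,41,34,29,21,20,19,16,13,8
mortality,female,colon,102,86,73,62,53,38,37,35,31,25,15
mortality,female,liver,24,20,17,14,12,9,8,8,7,5,3
mortality,female,lung,643,534,442,367,305,213,212,204,183,140,81
mortality,female,breast,274,214,167,130,101,61,35,19,9,5,2
mortality,female,uterus,11,10,8,7,6,4,4,3,3,2,1
mortality,female,ovary,55,47,39,34,28,20,20,18,15,10,5
mortality,female,bladder,59,51,43,36,31,23,23,22,22,19,13
mortality,female,other,491,287,220,179,147,103,97,86,69,47,24
mortality,female,all_solid,1717,1295,1051,862,711,491,455,415,354,265,152
mortality,female,leukemia,53,52,53,52,51,51,52,54,55,52,38
mortality,female,all_cancers,1770,1347,1104,914,762,542,507,469,409,317,190
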