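"patient_id","time_h","spo2","pao2","device","flow","fio2","map","gcs","platelets","bilirubin","creatinine","urine_output","norepinephrine","dobutamine","dopamine"
"P0001",4,86,,"ventilator",,0.75,56,7,122,2.05,2.01,713,0,10.139,0
"P0001",16,94,148,"nasal_cannula",12.6,,71,6,233,1.05,1.71,795,0,5.6,0
"P0001",28,95,,"nasal_cannula",14.1,,84,8,148,0.75,0.82,665,0,7.476,0
"P0001",44,86,,"nasal_cannula",9.7,,79,9,145,0.61,0.92,1452,0,8.628,0
"P0002",4,98,,"nasal_cannula",7.1,,81,10,234,1.33,1.92,1290,0.092,0,0
"P0002",16,,,"nasal_cannula",11.4,,71,14,227,1.81,1.23,1371,0.107,0,0
"P0002",28,100,,"room_air",,,108,15,333,0.21,0.44,1945,0.024,0,0
"P0002",44,100,,"room_air",,,109,15,413,0.23,0.47,2603,0.027,0,0
"P0003",4,90,,"nasal_cannula",5.6,,84,12,241,0.52,1.3,1042,0,0,0
"P0003",16,94,,"nasal_cannula",9.7,,73,10,212,0.46,1.28,1379,0,0,0
"P0003",28,100,,"nasal_cannula",14.1,,68,,211,1.08,1.62,1691,0,0,0
"P0003",44,95,,"nasal_cannula",11.2,,83,7,170,0.34,2.14,1514,0,0,0
"P0004",4,100,,"room_air",,,93,15,277,0.2,0.43,2511,0,0,0
"P0004",16,99,,"room_air",,,90,14,324,0.3,0.32,2220,0,0,0
"P0004",28,100,,"room_air",,,93,15,370,0.29,0.34,2074,0,0,0
"P0004",44,98,,"room_air",,,111,15,370,0.22,0.48,2309,0,0,0
"P0005",4,88,,"ventilator",,0.71,77,8,175,1.41,1.84,1297,0,0,0
"P0005",16,87,,"nasal_cannula",12.9,,71,5,124,2.02,1.1,850,0,0,0
"P0005",28,100,,"room_air",,,72,14,384,0.37,0.41,2449,0,0,0
"P0005",44,100,,"room_air",,,103,15,343,0.4,0.73,2051,0,0,0
"P0006",4,100,,"nasal_cannula",11.7,,89,15,214,0.43,1.07,1856,0,0,0
"P0006",16,94,163,"nasal_cannula",7.5,,83,7,350,1.12,0.63,1532,0,0,0
"P0006",28,97,,"nasal_cannula",8,,84,8,270,0.49,0.91,1496,0,0,0
"P0006",44,94,,"nasal_cannula",11.4,,71,11,242,0.53,1.36,1795,0,0,0
"P0007",4,94,,"nasal_cannula",13.5,,77,8,162,1.2,1.1,1168,0.101,0,0
"P0007",16,92,146,"nasal_cannula",9.8,,62,6,246,0.37,1.99,1272,0.09,0,0
"P0007",28,98,,"room_air",,,93,14,325,0.27,0.55,2364,0.04,0,0
"P0007",44,99,,"room_air",,,90,13,321,0.67,0.42,2140,0.051,0,0
"P0008",4,89,,"nasal_cannula",7.9,,73,10,283,0.94,1.41,1048,0,0,0
"P0008",16,97,,"nasal_cannula",6.6,,92,9,214,0.61,1.76,1827,0,0,0
"P0008",28,94,,"nasal_cannula",5.4,,86,15,258,0.38,0.36,1767,0,0,0
"P0008",44,100,,"room_air",,,102,14,343,0.28,0.67,1873,0,0,0
"P0009",4,98,,"room_air",,,92,12,240,0.21,0.52,1510,0,0,0
"P0009",16,98,,"nasal_cannula",3,,82,,272,0.39,1.05,1700,0,0,0
"P0009",28,100,,"room_air",,,107,15,395,0.25,0.43,2171,0,0,0
"P0009",44,100,,"room_air",,,119,15,445,0.16,0.36,1965,0,0,0
"P0010",4,100,148,"nasal_cannula",1.4,,90,15,274,0.26,0.57,1928,0,0,0
"P0010",16,94,,"room_air",,,91,13,335,0.32,0.69,1293,0,0,0
"P0010",28,94,,"nasal_cannula",14.1,,85,8,186,0.82,1.43,1474,0,0,0
"P0010",44,97,,"nasal_cannula",9.8,,70,,158,1.64,1.13,1442,0,0,0
"P0011",4,100,,"room_air",,,91,15,333,0.26,0.46,1800,0,0,0
"P0011",16,100,,"room_air",,,89,15,339,0.21,0.35,1863,0,0,0
"P0011",28,100,163,"room_air",,,101,15,425,0.1,0.44,2269,0,0,0
"P0011",44,100,,"room_air",,,108,15,350,0.2,0.33,2699,0,0,0
"P0012",4,94,,"nasal_cannula",12.9,,74,6,154,0.88,2.01,1995,0.074,0,0
"P0012",16,94,,"nasal_cannula",13.4,,68,8,179,0.66,2.06,1145,0.159,0,0
"P0012",28,82,,"nasal_cannula",13.5,,73,5,123,1.37,1.3,1129,0.106,0,0
"P0012",44,81,,"ventilator",,0.68,68,6,99,1.65,2.31,750,0.175,0,0
"P0013",4,96,,"nasal_cannula",3.8,,77,14,275,0.41,0.39,1798,0,0,0
"P0013",16,97,,"nasal_cannula",4.5,,78,14,292,0.53,0.74,1691,0,0,0
"P0013",28,92,,"nasal_cannula",8.8,,69,12,211,0.62,1.54,,0,0,0
"P0013",44,99,,"nasal_cannula",12.3,,78,9,266,0.86,1.04,1731,0,0,0
"P0014",4,90,,"nasal_cannula",10.1,,70,6,175,1.3,0.96,1149,0,0,0
"P0014",16,91,,"nasal_cannula",11,,90,11,201,0.74,1.5,1047,0,0,0
"P0014",28,93,,"nasal_cannula",9.1,,69,6,151,0.65,1.48,1185,0,0,0
"P0014",44,91,,"nasal_cannula",12,,86,10,175,0.59,1.15,1884,0,0,0
"P0015",4,100,,"room_air",,,116,15,521,0.1,0.2,2880,0,0,0
"P0015",16,100,,"room_air",,,129,15,487,0.1,0.2,3133,0,0,0
"P0015",28,100,,"room_air",,,118,15,590,0.1,0.2,3524,0,0,0
"P0015",44,100,,"room_air",,,121,15,636,0.1,0.2,3444,0,0,0
"P0016",4,97,157,"room_air",,,98,15,285,0.22,0.46,1970,0,0,0
"P0016",16,100,,"room_air",,,102,13,360,0.36,1.04,2068,0,0,0
"P0016",28,100,152,"room_air",,,98,15,333,0.13,0.97,2626,0,0,0
"P0016",44,95,,"room_air",,,86,14,304,0.3,0.48,2359,0,0,0
"P0017",4,100,163,"room_air",,,91,15,418,0.46,0.38,2519,0,0,0
"P0017",16,100,,"room_air",,,116,15,351,0.18,0.3,2056,0,0,0
"P0017",28,100,,"room_air",,,102,15,372,0.19,0.35,3036,0,0,0
"P0017",44,100,,"room_air",,,84,15,475,0.17,0.29,2214,0,0,0
"P0018",4,87,,"nasal_cannula",8.5,,87,9,297,0.51,0.96,1482,0,0,0
"P0018",16,96,,"nasal_cannula",10.5,,71,7,120,0.63,1.3,1226,0,0,0
"P0018",28,91,,"ventilator",,0.67,71,9,203,0.74,3.19,1224,0,0,0
"P0018",44,91,,"nasal_cannula",14,,72,6,224,1.81,1.24,1445,0,0,0
"P0019",4,100,,"room_air",,,96,14,359,0.21,1.03,1700,0,0,0
"P0019",16,100,,"room_air",,,102,15,348,0.23,0.62,2412,0,0,0
"P0019",28,99,,"room_air",,,93,15,460,0.23,0.26,2179,0,0,0
"P0019",44,100,,"room_air",,,94,15,321,0.35,0.76,1980,0,0,0
"P0020",4,100,,"room_air",,,94,15,355,0.23,0.6,2275,0,0,0
"P0020",16,100,,"room_air",,,96,15,351,0.26,0.49,,0,0,0
"P0020",28,100,,"nasal_cannula",9,,85,9,278,0.48,1.47,1256,0,0,0
"P0020",44,91,,"nasal_cannula",8.1,,77,10,212,0.8,1.82,1122,0,0,0
"P0021",4,93,,"nasal_cannula",13.5,,77,5,111,1.86,2.14,1307,0,6.141,0
"P0021",16,88,,"nasal_cannula",14.4,,81,11,181,1.9,1.22,1733,0,5.449,0
"P0021",28,96,151,"nasal_cannula",3.4,,73,10,333,0.2,0.52,1248,0,5.895,0
"P0021",44,98,,"nasal_cannula",2.3,,92,12,246,0.52,0.77,1366,0,3.775,0
"P0022",4,90,,"ventilator",,0.71,72,4,176,0.63,1.96,1692,0,0,0
"P0022",16,92,,"nasal_cannula",8.5,,86,8,188,0.39,1.55,1485,0,0,0
"P0022",28,88,,"nasal_cannula",14.9,,74,3,119,1.22,1.86,711,0,0,0
"P0022",44,87,,"nasal_cannula",12.6,,73,6,123,0.86,1.55,1292,0,0,0
"P0023",4,88,,"nasal_cannula",13.6,,80,7,154,0.95,3.78,1109,0,0,0
"P0023",16,91,,"nasal_cannula",14.4,,74,7,176,1.52,1.67,1387,0,0,0
"P0023",28,84,,"ventilator",,0.93,65,3,117,2.7,3.49,680,0,0,0
"P0023",44,79,,"ventilator",,0.92,58,3,66,1.53,2.64,,0,0,0
"P0024",4,93,,"nasal_cannula",2.5,,81,10,299,0.67,1.36,1562,0,0,0
"P0024",16,96,,"nasal_cannula",9.6,,75,12,226,0.28,1.73,1340,0,0,0
"P0024",28,84,,"ventilator",,0.69,72,5,118,1,2.28,1107,0,0,0
"P0024",44,91,,"ventilator",,0.68,76,7,180,0.81,1.68,1256,0,0,0
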