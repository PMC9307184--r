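sample_id,Otu001,Otu002,Otu003,Otu004,Otu005,Otu006,Otu007,Otu008,Otu009,Otu010,Otu011,Otu012,Otu013,Otu014,Otu015,Otu016,Otu017,Otu018,Otu019,Otu020
rat_01,289,16,47,18,19,326,2560,97,420,0,260,588,1,14,15,60,16,0,0,254
rat_02,1003,17,74,225,92,83,271,225,1561,7,271,744,1,4,60,63,28,0,10,261
rat_03,986,35,161,345,150,43,1311,10,357,42,292,799,16,46,14,193,40,2,5,153
rat_04,89,4,56,798,10,16,2434,251,147,4,434,596,3,10,37,78,1,2,0,30
rat_05,719,6,105,40,62,3,71,21,42,39,1740,1156,4,95,91,103,5,0,1,697
rat_06,36,17,59,957,109,90,58,26,284,14,53,2841,2,190,22,8,78,1,2,153
rat_07,208,11,168,354,274,41,96,37,521,27,405,1252,7,11,23,551,73,2,4,935
rat_08,7,1,2,22,4,1,2,3,4894,0,30,19,0,2,3,4,1,0,0,5
rat_09,20,7,11,687,37,187,430,41,66,7,200,2621,4,25,59,30,423,1,0,144
rat_10,273,25,51,402,19,144,1059,30,969,39,232,380,23,104,31,7,34,0,0,1178
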