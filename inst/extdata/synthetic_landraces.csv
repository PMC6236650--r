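sample_id,region,latitude,longitude,locus_01,locus_02,locus_03,locus_04,locus_05,locus_06,locus_07,locus_08,locus_09,locus_10,locus_11,locus_12,locus_13,locus_14,locus_15,locus_16,gbssi_s,gbssi_l
sim0001,deme_049,34,99,12,23,14,27,29,30,24,12,15,NA,13,29,30,12,23,20,S0/S0,LY/Lf
sim0002,deme_145,31,108,20,13,21,18,15,25,22,29,26,25,NA,30,23,17,29,11,S-15/S-15,LC/LY
sim0003,deme_065,39,100,27,29,24,11,13,21,30,20,23,19,26,11,12,26,26,17,S0/S-15,Lf/Lf
sim0004,deme_088,40,102,27,29,24,11,13,22,30,20,23,19,26,11,12,26,26,17,S0/S-15,LC/LY
sim0005,deme_165,40,109,10,15,20,19,21,26,25,16,10,14,30,13,12,27,14,14,S0/S0,LY/Lf
sim0006,deme_130,38,106,28,30,14,23,29,17,26,10,21,22,19,15,11,18,15,10,S0/S-15,LY/Lf
sim0007,deme_094,35,103,12,22,14,27,29,30,24,12,15,25,13,29,30,12,23,20,S0/S-15,LC/LC
sim0008,deme_010,39,95,12,23,14,27,29,30,24,12,15,25,13,29,30,12,23,20,S0/S-15,LC/LC
sim0009,deme_100,30,104,23,14,25,29,10,19,22,22,17,30,22,22,18,15,19,12,S-15/S-15,LY/Lf
sim0010,deme_198,40,112,25,18,26,17,12,14,27,23,20,12,24,29,25,29,23,13,S0/S0,LC/LY
sim0011,deme_081,33,102,15,21,15,17,12,18,28,25,26,30,25,12,21,25,20,24,S0/S-15,LC/LY
sim0012,deme_026,33,97,12,22,14,27,29,30,24,12,14,25,13,29,30,12,23,20,S0/S0,LC/LY
sim0013,deme_160,35,109,25,25,17,15,15,18,12,23,13,15,25,10,20,22,20,20,S-15/S-15,Lf/Lf
sim0014,deme_160,35,109,17,28,11,11,13,30,18,16,22,29,30,23,25,12,29,23,S0/S0,LC/LC
sim0015,deme_199,30,113,25,25,17,15,15,19,12,23,13,15,25,10,20,22,20,20,S-15/S-15,Lf/Lf
sim0016,deme_154,40,108,10,15,20,19,21,26,25,16,10,14,30,13,12,27,14,14,S0/S0,LC/LC
sim0017,deme_166,30,110,25,25,17,15,15,18,12,23,13,15,25,10,20,22,20,20,S0/S-15,LC/LC
sim0018,deme_191,33,112,17,28,11,11,13,30,18,16,22,29,30,23,25,12,29,23,S0/S0,Lf/Lf
sim0019,deme_078,30,102,13,24,23,24,18,29,25,14,10,28,25,17,12,13,18,28,S0/S0,Lf/Lf
sim0020,deme_086,38,102,27,29,24,11,13,21,30,20,23,19,26,11,12,26,26,17,S0/S0,Lf/Lf
sim0021,deme_135,32,107,15,21,15,17,12,18,28,25,26,30,25,12,21,25,20,24,S0/S0,LC/LY
sim0022,deme_098,39,103,10,15,20,19,21,26,25,16,10,14,30,13,12,27,14,NA,S0/S0,Lf/Lf
sim0023,deme_125,33,106,17,28,11,11,13,30,18,16,22,29,30,23,25,12,29,23,S0/S0,LY/Lf
sim0024,deme_011,40,95,NA,12,23,18,18,23,16,15,26,22,15,17,10,12,20,12,S-15/S-15,LC/LC
sim0025,deme_159,34,109,17,28,11,11,13,30,18,16,22,29,30,23,25,12,29,23,S0/S0,Lf/Lf
sim0026,deme_180,33,111,25,25,17,15,15,18,12,23,13,15,25,10,20,22,20,20,S-15/S-15,LC/LC
sim0027,deme_049,34,99,12,23,14,27,29,30,24,12,15,25,13,29,30,12,23,20,S0/S0,LC/LY
sim0028,deme_048,33,99,12,23,NA,27,29,30,24,12,15,25,13,29,30,12,23,20,S0/S0,LY/Lf
sim0029,deme_076,39,101,27,29,24,11,13,21,30,20,23,19,26,11,12,26,25,17,S0/S-15,LY/Lf
sim0030,deme_115,34,105,25,25,20,NA,24,23,22,26,15,26,10,22,10,28,21,27,S-15/S-15,Lf/Lf
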