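genotype,Ys,Yp,STI,GMP,MP,TOL,HM,YSI,YI,SSI,ref_R,ref_SDR,ref_RS
SY010,1,44,2,2,7,22,2,8,1,9,9.8,13.61209,23.41209
SY032,2,39,6,3,8,29,3,23,4,28,14.5,13.78606,28.28606
SY095,5,54,10,9,20,26,5,14,5,15,16.3,14.95215,31.25215
SY101,9,48,13,11,19,42,9,17,10,19,19.7,13.94473,33.64473
SY043,11,53,7,13,24,38,10,21,8,22,20.7,14.80278,35.50278
SY098,12,55,22,17,27,41,11,16,11,16,22.8,14.55869,37.35869
SY005,3,79,8,10,26,8,4,6,2,7,15.3,23.37639,38.67639
SY150,10,22,3,6,9,71,7,26,6,25,18.5,20.31557,38.81557
SY047,8,35,12,7,13,56,6,37,12,39,22.5,17.62101,40.12101
SY052,6,84,29,23,41,11,12,5,9,3,22.3,24.833,47.133
SY094,4,8,1,1,2,94,1,34,3,37,18.5,29.87846,48.37846
SY013,16,75,33,30,46,30,21,27,16,29,32.3,17.38486,49.68486
SY104,15,36,24,14,22,75,14,42,20,45,30.7,19.32787,50.02787
SY100,17,16,14,12,11,98,15,25,14,23,24.5,26.20963,50.70963
SY096,24,42,28,24,30,83,23,36,25,36,35.1,17.9966,53.0966
SY011,27,72,34,39,52,46,33,33,27,33,39.6,13.84197,53.44197
SY105,7,95,35,25,50,7,17,2,7,2,24.7,29.28424,53.98424
SY119,29,49,32,31,38,77,28,46,30,47,40.7,15.07057,55.77057
SY022,23,81,48,40,54,34,31,18,24,17,37,19.79338,56.79338
SY075,20,29,9,19,21,93,19,52,17,55,33.4,25.81214,59.21214
SY097,22,24,17,20,18,100,20,49,22,50,34.2,26.16529,60.36529
SY099,19,23,16,15,17,96,18,55,21,59,33.9,27.19252,61.09252
SY124,45,57,36,44,51,76,42,53,42,53,49.9,11.1997,61.0997
SY045,33,41,40,29,35,87,27,54,41,58,44.5,17.92732,62.42732
SY117,14,7,4,4,3,121,8,47,13,46,26.7,37.05267,63.75267
SY142,34,45,31,32,36,86,30,61,34,64,45.3,18.88591,64.18591
SY112,47,70,51,46,58,64,43,59,48,65,55.1,9.338689,64.43869
SY092,36,47,15,34,40,84,32,63,31,66,44.8,20.49824,65.29824
SY147,41,32,27,41,32,107,44,38,32,32,42.6,23.25797,65.85797
SY053,35,86,62,49,66,35,41,35,45,38,49.2,17.04765,66.24765
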