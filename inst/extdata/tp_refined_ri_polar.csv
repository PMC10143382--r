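compound,rt_min,mw,detected,ri_obs,ri_pred_1,ri_pred_2,ri_source,nist_spectrum,note
1,4.75,82,TRUE,1119,1163,NA,ML,TRUE,
2,6.44,96,TRUE,1215,1273,NA,ML,TRUE,
3,9.02,97,TRUE,1362,1427,1410,ML,FALSE,
4,9.72,126,TRUE,1406,1500,NA,ML,FALSE,
5,10.24,83,TRUE,1440,1463,1354,ML,TRUE,
6,10.71,97,TRUE,1470,1526,NA,ML,FALSE,
7,12.52,96,TRUE,1591,1680,NA,NIST,TRUE,
8,14.00,126,TRUE,1704,1730,NA,ML,FALSE,
9,14.52,82,TRUE,1739,1690,NA,NIST,TRUE,
10,15.33,130,TRUE,1801,1754,NA,ML,TRUE,
11,16.95,121,TRUE,1932,1886,NA,ML,TRUE,
12,18.25,152,TRUE,2041,1963,NA,ML,FALSE,
13,18.35,127,TRUE,2050,2146,NA,ML,FALSE,
14,18.80,166,TRUE,2090,2147,2079,ML,TRUE,
15,18.82,152,TRUE,2092,2031,NA,ML,FALSE,
16,21.20,112,TRUE,2312,2246,NA,ML,FALSE,
17,21.28,153,TRUE,2320,2261,NA,ML,FALSE,
18,22.67,153,TRUE,2456,2390,NA,ML,FALSE,
19,22.87,153,TRUE,2476,2397,NA,ML,FALSE,
20,24.71,153,TRUE,2670,2629,NA,ML,FALSE,
21,27.66,169,TRUE,3005,2927,NA,ML,FALSE,
22,NA,102,FALSE,NA,NA,NA,ML,TRUE,
23,NA,85,FALSE,NA,NA,NA,ML,TRUE,solvent cut
24,NA,73,FALSE,NA,NA,NA,ML,TRUE,
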