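compound,rt_min,ri_polar_obs,ri_polar_pred,ri_nonpolar_obs,ri_nonpolar_pred,epa_category
I,13.65,1681,1615,1177,1131,II
II,18.11,2030,2077,1295,1275,III
III,19.74,2175,2255,1427,1387,III
IV,25.82,2792,2768,1841,1821,II
V,26.34,2851,2879,1983,1944,II
VI,28.75,3132,3027,2010,1994,II
VII,29.43,3201,3240,1733,1726,II
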