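zone;bmd_hologic;bmd_standardized;apparent_density;youngs_modulus
1;782;794;1,480;9287
2;1093;1108;1,669;13333
3;1429;1446;1,837;17810
4;1591;1610;1,909;20000
5;1530;1548;1,882;19173
6;1302;1318;1,777;16107
7;1192;1208;1,721;14642
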