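zone,device,bmd
1,hologic,782
2,hologic,1093
3,hologic,1429
4,hologic,1591
5,hologic,1530
6,hologic,1302
7,hologic,1192
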