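"mass_pg","signal"
100,1474.1
200,2642.8
400,5031.3
800,9766.8
1200,14445.7
1600,19519.8
2000,24032.8
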