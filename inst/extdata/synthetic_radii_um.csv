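"radius_um"
9.16
8.33
7.37
9.43
8.19
10.68
9.34
8.86
9.61
9.7
8.2
9.8
9.96
9.5
9.93
9.96
9.22
8.33
10.17
10.04
8.42
8.84
7.95
9.5
8.13
10.03
7.97
9.07
8.14
7.72
10.01
8.55
9.33
7.19
8.99
9.45
10.09
10.43
9.35
8.65
8.68
7.67
7.52
8.53
9.2
10.17
9.79
10.08
8.77
7.03
7.99
9.7
8.97
10.01
9.03
8.08
8.46
9.37
7.91
9.87
10.57
9.79
9.55
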