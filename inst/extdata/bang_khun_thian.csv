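pm25
24.00
29.42
44.08
45.64
67.38
84.54
62.17
25.63
19.04
35.29
37.14
35.71
62.58
99.38
112.08
73.70
71.67
33.27
58.79
93.58
100.33
130.67
76.83
36.38
36.29
37.63
37.00
42.25
39.17
53.50
49.96
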