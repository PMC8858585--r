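pm25
27.54
32.58
47.29
54.88
42.25
47.46
37.83
29.88
23.58
32.63
35.75
30.00
52.92
77.00
93.46
105.79
60.46
34.63
53.96
77.79
82.08
91.88
89.71
47.96
44.83
41.33
49.46
51.00
49.04
51.58
50.26
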