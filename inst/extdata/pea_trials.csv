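t1,t2,t3,t4,w1,w2,w3,target
24.7,21.5,24.2,22.6,200,200,200,0.73
24.6,19.8,24.5,24.1,200,195,213,0.41
25.9,22.0,25.1,22.0,200,182,203,0.69
24.9,21.4,24.2,23.0,200,200,197,0.49
25.1,24.8,26.8,27.8,196,3,179,0.82
23.0,21.3,27.8,26.6,187,208,206,0.66
24.7,21.6,24.3,22.4,200,197,207,0.69
25.0,22.5,24.3,21.4,200,195,202,0.51
20.6,26.7,29.3,28.8,178,9,179,0.54
25.1,24.8,26.8,27.8,196,3,179,0.87
21.7,26.2,28.6,28.6,182,8,179,0.91
26.5,27.7,25.7,26.6,159,10,169,0.77
21.6,26.3,28.7,28.6,182,8,179,0.81
25.6,21.7,24.3,22.1,204,189,201,0.58
26.0,21.8,25.8,26.8,195,178,227,0.78
28.2,24.1,26.6,28.9,228,18,235,0.73
27.5,24.7,24.0,30.1,23,95,248,0.54
30.4,21.0,34.3,23.7,24,10,250,0.67
26.4,22.2,29.9,25.6,170,39,144,0.89
25.8,23.7,29.6,25.2,173,39,162,1.13
25.8,25.7,30.2,25.5,249,45,108,0.69
22.4,22.4,32.4,25.2,127,52,201,0.70
23.3,22.3,31.6,26.0,139,52,188,0.98
21.0,20.6,30.1,23.2,146,30,186,0.55
24.0,23.9,32.7,24.5,125,61,194,0.87
24.2,23.2,31.8,25.0,136,54,184,0.97
25.7,24.7,32.7,26.6,138,73,188,0.77
22.4,20.8,29.6,23.3,147,18,164,0.78
23.0,21.6,29.8,24.0,150,27,166,1.00
22.7,22.5,29.8,22.7,156,26,172,0.69
24.0,21.6,28.9,23.6,160,28,157,0.68
24.1,22.0,29.0,23.9,162,32,160,1.10
24.0,22.4,29.0,23.1,167,32,165,0.92
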