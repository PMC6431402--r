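feature_id,feature_name,mean_class_su,selected_times
1,Alpha peak,0.042,0
2,Alpha average value,0.061,2
3,Alpha variance,0.035,0
4,Alpha centre frequency,0.146,28
5,Alpha maximum power,0.024,0
6,Alpha power sum,0.021,0
7,Theta peak,0.019,0
8,Theta average value,0.127,41
9,Theta variance,0.031,0
10,Theta centre frequency,0.189,26
11,Theta maximum power,0.072,7
12,Theta power sum,0.012,0
13,Beta peak,0.031,0
14,Beta average value,0.194,40
15,Beta variance,0.014,0
16,Beta centre frequency,0.124,27
17,Beta maximum power,0.101,21
18,Beta power sum,0.023,0
19,Singular spectral entropy,0.055,19
20,Entropy of K,0.202,30
21,Approximate entropy,0.138,27
22,Maximum Lyapunov exponent,0.129,35
23,Complexity of C0,0.121,31
24,Sample entropy,0.061,18
25,Spectral entropy,0.183,39
26,Lempel-Ziv complexity,0.211,40
27,Correlation dimension,0.074,19
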