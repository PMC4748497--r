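age,ssa_10y,adj_10y,ssa_15y,adj_15y
50,8,6,14,11
51,8,7,15,12
52,9,7,16,13
53,10,8,17,14
54,10,8,19,15
55,11,9,20,16
56,12,10,21,17
57,13,10,23,19
58,14,11,25,20
59,15,12,26,21
60,16,13,28,23
61,17,14,31,25
62,18,15,33,26
63,20,16,35,28
64,22,17,38,31
65,23,18,41,33
66,25,20,44,35
67,27,22,47,38
68,30,23,51,41
69,32,25,54,44
70,35,27,58,47
71,37,30,61,51
72,40,32,65,54
73,43,35,69,58
74,47,37,73,61
75,50,40,77,65
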