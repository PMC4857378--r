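frame,width_cm,height_cm
1,24.75,15.41
2,24.75,15.41
3,24.75,15.41
4,24.95,15.41
5,25.12,15.22
6,24.75,14.84
7,24.89,14.94
8,24.92,14.94
9,25.1,14.84
10,25.25,14.94
11,25,15.41
12,25,15.41
13,25,14.75
14,24.75,15.41
15,24.75,14.56
16,25.8,14.56
17,24.75,14.56
18,24.89,15.22
19,24.83,14.66
20,24.93,14.66
21,24.95,14.66
22,25,15.22
23,25,14.66
24,25,14.56
25,25.2,14.66
26,25.1,14.66
27,25,14.66
28,25.12,15.22
29,25.14,15.75
30,25.2,15.03
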