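patient_id,hypointense_m24_ml,tll_m24_ml,active,group
6,13.40,18.9,1,A
24,3.35,4.63,0,C
11,1.80,9.70,1,B
4,1.77,4.29,1,A
16,1.46,4.70,1,A
9,1.42,6.72,1,A
10,1.37,4.82,1,A
25,0.96,3.32,1,B
7,0.82,2.10,1,B
18,0.75,3.40,1,B
21,0.74,3.50,1,B
17,0.52,1.18,1,B
2,0.46,1.90,1,B
12,0.34,2.10,1,B
8,0.31,1.14,1,B
3,0.28,0.98,0,C
19,0.27,1.73,1,B
20,0.18,0.54,0,C
5,0.14,1.70,1,B
15,0.13,0.68,0,C
13,0.12,3.54,1,B
1,0.12,1.18,0,C
22,0.10,1.27,1,B
23,0.06,0.49,0,C
14,0.00,0.29,0,C
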