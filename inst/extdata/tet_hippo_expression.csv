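sample_id,group,target_id,fold_change,log2fc
1,N,MST1,1.42,0.51
1,N,SAV1,0.92,-0.13
1,N,LATS1,1.12,0.16
1,N,MOB1A,0.95,-0.07
1,N,YAP1,0.91,-0.13
1,N,TEAD4,0.84,-0.26
2,N,MST1,1.34,0.42
2,N,SAV1,1.53,0.62
2,N,LATS1,1.76,0.82
2,N,MOB1A,1.13,0.18
2,N,YAP1,2.25,1.17
2,N,TEAD4,0.94,-0.08
3,N,MST1,0.7,-0.51
3,N,SAV1,1.09,0.13
3,N,LATS1,0.89,-0.16
3,N,MOB1A,1.05,0.07
3,N,YAP1,1.1,0.13
3,N,TEAD4,1.2,0.26
4,A,MST1,2.66,1.41
4,A,SAV1,2.52,1.34
4,A,LATS1,1.09,0.13
4,A,MOB1A,1.68,0.75
4,A,YAP1,3.98,1.99
4,A,TEAD4,2.17,1.12
5,A,MST1,0.9,-0.15
5,A,SAV1,14.07,3.82
5,A,LATS1,2.05,1.04
5,A,MOB1A,1.06,0.08
5,A,YAP1,10.76,3.43
5,A,TEAD4,5.07,2.34
6,A,MST1,0.5,-1.01
6,A,SAV1,4.76,2.25
6,A,LATS1,1.09,0.13
6,A,MOB1A,1.17,0.22
6,A,YAP1,13.11,3.71
6,A,TEAD4,3.33,1.74
7,B1,MST1,0.58,-0.78
7,B1,SAV1,0.72,-0.48
7,B1,LATS1,0.94,-0.09
7,B1,MOB1A,0.91,-0.13
7,B1,YAP1,1.08,0.11
7,B1,TEAD4,1.24,0.31
8,B1,MST1,0.64,-0.65
8,B1,SAV1,1.54,0.63
8,B1,LATS1,0.56,-0.83
8,B1,MOB1A,0.78,-0.37
8,B1,YAP1,1.84,0.88
8,B1,TEAD4,1.28,0.36
9,B1,MST1,0.98,-0.03
9,B1,SAV1,1.15,0.2
9,B1,LATS1,1.15,0.2
9,B1,MOB1A,0.78,-0.36
9,B1,YAP1,1.5,0.59
9,B1,TEAD4,0.75,-0.41
10,B1,MST1,0.48,-1.07
10,B1,SAV1,0.8,-0.32
10,B1,LATS1,0.52,-0.93
10,B1,MOB1A,1.15,0.2
10,B1,YAP1,1.13,0.18
10,B1,TEAD4,2.13,1.09
11,B1,MST1,0.62,-0.68
11,B1,SAV1,0.56,-0.82
11,B1,LATS1,0.38,-1.4
11,B1,MOB1A,0.98,-0.02
11,B1,YAP1,0.73,-0.45
11,B1,TEAD4,0.62,-0.69
12,B2,MST1,1.13,0.17
12,B2,SAV1,1.2,0.26
12,B2,LATS1,1.08,0.1
12,B2,MOB1A,0.89,-0.16
12,B2,YAP1,1.57,0.65
12,B2,TEAD4,0.88,-0.19
13,B2,MST1,0.64,-0.65
13,B2,SAV1,1.6,0.67
13,B2,LATS1,0.75,-0.42
13,B2,MOB1A,1.04,0.05
13,B2,YAP1,1.67,0.74
13,B2,TEAD4,0.27,-1.9
14,B2,MST1,0.76,-0.39
14,B2,SAV1,1.74,0.8
14,B2,LATS1,0.53,-0.91
14,B2,MOB1A,1.11,0.15
14,B2,YAP1,2.68,1.42
14,B2,TEAD4,1.01,0.01
15,B2,MST1,0.94,-0.09
15,B2,SAV1,4.38,2.13
15,B2,LATS1,1.26,0.33
15,B2,MOB1A,1.21,0.28
15,B2,YAP1,4.34,2.12
15,B2,TEAD4,4.97,2.31
16,B2,MST1,0.96,-0.06
16,B2,SAV1,1.72,0.78
16,B2,LATS1,1.09,0.13
16,B2,MOB1A,1.22,0.29
16,B2,YAP1,1.28,0.35
16,B2,TEAD4,1.39,0.48
17,B3,MST1,0.69,-0.53
17,B3,SAV1,2.7,1.44
17,B3,LATS1,0.98,-0.03
17,B3,MOB1A,1.24,0.31
17,B3,YAP1,4.15,2.05
17,B3,TEAD4,1.38,0.47
18,B3,MST1,2.1,1.07
18,B3,SAV1,3.96,1.99
18,B3,LATS1,1.5,0.59
18,B3,MOB1A,1.47,0.56
18,B3,YAP1,6.86,2.78
18,B3,TEAD4,0.96,-0.06
19,B3,MST1,0.76,-0.4
19,B3,SAV1,4.03,2.01
19,B3,LATS1,0.58,-0.78
19,B3,MOB1A,0.96,-0.06
19,B3,YAP1,5.61,2.49
19,B3,TEAD4,3.84,1.94
20,B3,MST1,1.15,0.2
20,B3,SAV1,7.54,2.92
20,B3,LATS1,1.1,0.14
20,B3,MOB1A,2.05,1.04
20,B3,YAP1,12.79,3.68
20,B3,TEAD4,5.21,2.38
21,B3,MST1,0.83,-0.26
21,B3,SAV1,6.57,2.72
21,B3,LATS1,0.8,-0.32
21,B3,MOB1A,1.25,0.33
21,B3,YAP1,7.15,2.84
21,B3,TEAD4,2.93,1.55
22,TC,MST1,0.43,-1.21
22,TC,SAV1,3.67,1.88
22,TC,LATS1,0.74,-0.43
22,TC,MOB1A,0.73,-0.45
22,TC,YAP1,3.11,1.64
22,TC,TEAD4,4.83,2.27
23,TC,MST1,0.07,-3.83
23,TC,SAV1,0.57,-0.81
23,TC,LATS1,0.14,-2.87
23,TC,MOB1A,2.3,1.2
23,TC,YAP1,3.23,1.69
23,TC,TEAD4,17.48,4.13
24,TC,MST1,0.38,-1.38
24,TC,SAV1,0.82,-0.28
24,TC,LATS1,0.63,-0.67
24,TC,MOB1A,0.91,-0.14
24,TC,YAP1,1.4,0.48
24,TC,TEAD4,3.05,1.61
25,TC,MST1,0.26,-1.93
25,TC,SAV1,1.59,0.67
25,TC,LATS1,0.33,-1.62
25,TC,MOB1A,0.71,-0.49
25,TC,YAP1,0.96,-0.06
25,TC,TEAD4,11.22,3.49
26,TC,MST1,0.52,-0.94
26,TC,SAV1,2.17,1.12
26,TC,LATS1,0.39,-1.34
26,TC,MOB1A,0.96,-0.06
26,TC,YAP1,3.19,1.67
26,TC,TEAD4,12.19,3.61
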