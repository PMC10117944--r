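dose,survivors,total,replicate
0,30,30,1
0,30,30,2
0,30,30,3
50,29,30,1
50,28,30,2
50,30,30,3
100,24,30,1
100,20,30,2
100,24,30,3
150,16,30,1
150,15,30,2
150,15,30,3
200,10,30,1
200,10,30,2
200,14,30,3
250,9,30,1
250,12,30,2
250,9,30,3
300,3,30,1
300,3,30,2
300,4,30,3
400,0,30,1
400,3,30,2
400,0,30,3
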