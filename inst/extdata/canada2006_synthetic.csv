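age_lo,age_hi,sex,proportion
40,45,F,0.0842306000000001
45,50,F,0.0835972
50,55,F,0.0759975
55,60,F,0.0683977
60,65,F,0.0538315
65,70,F,0.0430652
70,75,F,0.0367321
75,80,F,0.0322989
80,85,F,0.0253325
85,90,F,0.0158328
40,45,M,0.0829639
45,50,M,0.0816973
50,55,M,0.0740975
55,60,M,0.0664978
60,65,M,0.0519316
65,70,M,0.0398987
70,75,M,0.0322989
75,80,M,0.0259658
80,85,M,0.0170994
85,90,M,0.0082331
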