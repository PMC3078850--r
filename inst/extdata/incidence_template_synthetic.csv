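sex,age,p0
F,40,0
F,41,0.000898
F,42,0.001886
F,43,0.002972
F,44,0.004166
F,45,0.005476
F,46,0.006914
F,47,0.00849
F,48,0.010218
F,49,0.012109
F,50,0.014177
F,51,0.016437
F,52,0.018903
F,53,0.021591
F,54,0.024517
F,55,0.027697
F,56,0.031148
F,57,0.034886
F,58,0.038929
F,59,0.043291
F,60,0.047988
F,61,0.053034
F,62,0.05844
F,63,0.064218
F,64,0.070374
F,65,0.076913
F,66,0.083838
F,67,0.091143
F,68,0.098824
F,69,0.106868
F,70,0.115258
F,71,0.123972
F,72,0.132985
F,73,0.142264
F,74,0.151772
F,75,0.16147
F,76,0.171314
F,77,0.181256
F,78,0.191247
F,79,0.201239
F,80,0.211181
F,81,0.221024
F,82,0.230723
F,83,0.240231
F,84,0.24951
F,85,0.258523
F,86,0.267237
F,87,0.275627
F,88,0.283671
F,89,0.291352
M,40,0
M,41,0.001774
M,42,0.003717
M,43,0.005845
M,44,0.008171
M,45,0.010713
M,46,0.013488
M,47,0.016512
M,48,0.019803
M,49,0.023381
M,50,0.027263
M,51,0.031469
M,52,0.036017
M,53,0.040924
M,54,0.046208
M,55,0.051885
M,56,0.057967
M,57,0.064467
M,58,0.071393
M,59,0.07875
M,60,0.086539
M,61,0.094758
M,62,0.103399
M,63,0.112448
M,64,0.121887
M,65,0.131691
M,66,0.14183
M,67,0.152269
M,68,0.162966
M,69,0.173876
M,70,0.18495
M,71,0.196135
M,72,0.207375
M,73,0.218616
M,74,0.229801
M,75,0.240875
M,76,0.251785
M,77,0.262482
M,78,0.272921
M,79,0.28306
M,80,0.292864
M,81,0.302303
M,82,0.311352
M,83,0.319992
M,84,0.328212
M,85,0.336001
M,86,0.343358
M,87,0.350284
M,88,0.356784
M,89,0.362866
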