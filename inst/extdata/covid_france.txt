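# Daily COVID-19 mortality-rate proxies, France, 1 March - 16 June 2021 (108 days)
# x_i = ND_i / (CC_i - CD_{i-1}) * 1000
0.0024
0.0025
0.0027
0.0045
0.0045
0.0062
0.0109
0.0113
0.0123
0.0123
0.0126
0.0129
0.0130
0.0139
0.0152
0.0160
0.0160
0.0161
0.0164
0.0169
0.0173
0.0174
0.0188
0.0219
0.0225
0.0226
0.0248
0.0260
0.0284
0.0303
0.0315
0.0318
0.0320
0.0323
0.0327
0.0329
0.0332
0.0343
0.0345
0.0346
0.0346
0.0347
0.0347
0.0352
0.0359
0.0365
0.0366
0.0370
0.0371
0.0376
0.0384
0.0392
0.0396
0.0419
0.0421
0.0443
0.0445
0.0462
0.0492
0.0506
0.0525
0.0536
0.0539
0.0540
0.0568
0.0569
0.0592
0.0600
0.0603
0.0606
0.0617
0.0619
0.0621
0.0629
0.0632
0.0657
0.0665
0.0675
0.0678
0.0683
0.0684
0.0691
0.0693
0.0707
0.0708
0.0719
0.0722
0.0727
0.0771
0.0773
0.0773
0.0774
0.0791
0.0832
0.0837
0.0845
0.0865
0.0897
0.0907
0.0910
0.0946
0.0961
0.0972
0.1010
0.1056
0.1123
0.1149
0.2153
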