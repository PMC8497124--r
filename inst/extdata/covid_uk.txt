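# Daily COVID-19 mortality-rate proxies, United Kingdom, 1 May - 16 July 2021 (82 days)
# x_i = ND_i / (CC_i - CD_{i-1}) * 1000
0.0023
0.0023
0.0023
0.0046
0.0065
0.0067
0.0069
0.0069
0.0091
0.0093
0.0093
0.0093
0.0111
0.0115
0.0116
0.0116
0.0119
0.0133
0.0136
0.0138
0.0138
0.0159
0.0161
0.0162
0.0162
0.0162
0.0163
0.0180
0.0187
0.0202
0.0207
0.0208
0.0225
0.0230
0.0230
0.0239
0.0245
0.0251
0.0255
0.0255
0.0271
0.0275
0.0295
0.0297
0.0300
0.0302
0.0312
0.0314
0.0326
0.0346
0.0349
0.0350
0.0355
0.0379
0.0384
0.0394
0.0394
0.0412
0.0419
0.0425
0.0461
0.0464
0.0468
0.0471
0.0495
0.0501
0.0521
0.0571
0.0588
0.0597
0.0628
0.0679
0.0685
0.0715
0.0766
0.0780
0.0942
0.0960
0.0988
0.1223
0.1343
0.1781
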