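channels:
- index: 0
  ex_center_nm: 334.0
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex334
- index: 1
  ex_center_nm: 343.4705882
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex343
- index: 2
  ex_center_nm: 352.9411765
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex353
- index: 3
  ex_center_nm: 362.4117647
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex362
- index: 4
  ex_center_nm: 371.8823529
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex372
- index: 5
  ex_center_nm: 381.3529412
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex381
- index: 6
  ex_center_nm: 390.8235294
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex391
- index: 7
  ex_center_nm: 400.2941176
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex400
- index: 8
  ex_center_nm: 409.7647059
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex410
- index: 9
  ex_center_nm: 419.2352941
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex419
- index: 10
  ex_center_nm: 428.7058824
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex429
- index: 11
  ex_center_nm: 438.1764706
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex438
- index: 12
  ex_center_nm: 447.6470588
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex448
- index: 13
  ex_center_nm: 457.1176471
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex457
- index: 14
  ex_center_nm: 466.5882353
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex467
- index: 15
  ex_center_nm: 476.0588235
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex476
- index: 16
  ex_center_nm: 485.5294118
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex486
- index: 17
  ex_center_nm: 495.0
  ex_bw_nm: 10.0
  em_low_nm: 450.0
  em_high_nm: 700.0
  label: ex495
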