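features:
- name: mean_ex360
  family: mean_intensity
  channel: 4
- name: mean_ex460
  family: mean_intensity
  channel: 14
- name: ratio_360_460
  family: band_ratio
  num_channel: 4
  den_channel: 14
- name: ratio_ch3_ch15
  family: band_ratio
  num_channel: 3
  den_channel: 15
- name: ratio_ch5_ch6
  family: band_ratio
  num_channel: 5
  den_channel: 6
- name: ratio_ch8_ch14
  family: band_ratio
  num_channel: 8
  den_channel: 14
- name: pc1_variance
  family: pca_stat
  component: 1
  statistic: variance
- name: pc2_skewness
  family: pca_stat
  component: 2
  statistic: skewness
- name: pc3_mean
  family: pca_stat
  component: 3
  statistic: mean
- name: corr_360_460
  family: channel_correlation
  channel_a: 4
  channel_b: 14
- name: corr_ch3_ch15
  family: channel_correlation
  channel_a: 3
  channel_b: 15
- name: corr_ch5_ch6
  family: channel_correlation
  channel_a: 5
  channel_b: 6
- name: spectral_variation
  family: spectral_variation
- name: texture_ch4_contrast
  family: texture
  channel: 4
  metric: glcm_contrast
  levels: 16
  distance_px: 1
- name: texture_ch6_contrast
  family: texture
  channel: 6
  metric: glcm_contrast
  levels: 16
  distance_px: 1
- name: area
  family: morphology
  property: area_px
- name: perimeter
  family: morphology
  property: perimeter_px
- name: eccentricity
  family: morphology
  property: eccentricity
- name: solidity
  family: morphology
  property: solidity
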