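ch,mean_before_um,sd_before_um,cov_before_pct,mean_pn_um,sd_pn_um,cov_pn_pct,mean_pn_foa_um,sd_pn_foa_um,cov_pn_foa_pct
1,59.27,13.13,22.16,59.13,13.17,22.28,57.42,12.81,22.31
2,55.14,14.23,25.80,54.07,14.46,26.74,58.84,13.67,23.23
3,40.21,11.61,28.87,40.80,11.88,29.12,43.98,13.43,30.54
4,45.48,14.12,31.03,46.26,13.87,29.97,42.01,12.43,29.57
5,62.89,13.41,21.33,61.40,13.01,21.29,58.86,13.00,22.08
6,78.65,14.47,18.40,80.14,13.21,16.49,78.74,13.63,17.31
7,70.33,17.76,25.26,70.77,17.27,24.20,74.73,15.81,21.16
8,36.60,10.37,28.33,36.12,9.15,25.32,41.62,11.47,27.57
9,32.90,7.78,23.65,32.91,7.72,23.44,30.50,6.70,21.96
10,45.78,10.46,22.84,45.42,9.13,20.10,42.59,8.62,20.24
11,70.57,14.10,19.99,72.85,13.51,18.54,71.14,14.60,20.52
12,62.66,14.71,23.47,62.29,13.24,21.26,64.12,13.48,21.03
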