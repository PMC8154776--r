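population,upcr_g,n,median_uacr,q1,q3
all,0.01,41,8.0,6.0,15.0
all,0.02,58,10.5,7.0,15.0
all,0.03,67,11.0,7.0,17.0
all,0.04,64,16.0,10.0,28.0
all,0.05,58,17.5,10.3,29.0
all,0.06,65,21.0,12.0,37.0
all,0.07,56,29.5,13.0,41.0
all,0.08,36,26.0,18.0,53.3
all,0.09,40,39.0,24.8,57.3
all,0.10,28,51.0,35.8,63.0
all,0.11,26,60.5,44.3,73.5
all,0.12,29,57.0,34.0,78.0
all,0.13,23,71.0,55.0,92.0
all,0.14,27,67.0,40.0,88.0
all,0.15,25,71.0,48.0,104.0
all,0.16,25,95.0,53.0,120.0
non_diabetic,0.01,24,8.0,5.8,12.5
non_diabetic,0.02,35,8.0,6.0,15.5
non_diabetic,0.03,42,12.0,8.3,17.0
non_diabetic,0.04,39,19.0,9.0,32.0
non_diabetic,0.05,35,18.0,10.5,27.0
non_diabetic,0.06,43,19.0,11.5,36.5
non_diabetic,0.07,37,28.0,12.0,35.0
non_diabetic,0.08,25,25.0,14.0,53.0
non_diabetic,0.09,27,43.0,25.0,57.5
non_diabetic,0.10,22,48.0,36.5,58.8
non_diabetic,0.11,16,68.0,58.3,77.3
non_diabetic,0.12,18,59.0,46.3,79.3
non_diabetic,0.13,13,79.0,55.0,101.0
non_diabetic,0.14,18,78.5,39.0,104.3
non_diabetic,0.15,18,72.5,50.3,104.8
non_diabetic,0.16,13,116.0,79.0,133.0
diabetic,0.01,17,8.0,6.0,20.0
diabetic,0.02,23,12.0,8.5,13.5
diabetic,0.03,25,11.0,6.0,18.0
diabetic,0.04,25,12.0,10.0,27.0
diabetic,0.05,23,17.0,11.0,27.5
diabetic,0.06,22,25.0,14.0,36.8
diabetic,0.07,19,41.0,25.0,47.0
diabetic,0.08,11,32.0,22.0,45.5
diabetic,0.09,13,32.0,23.0,43.0
diabetic,0.10,6,63.0,42.0,66.8
diabetic,0.11,10,46.0,42.3,54.8
diabetic,0.12,11,52.0,32.5,71.5
diabetic,0.13,10,64.0,55.8,77.8
diabetic,0.14,9,51.0,48.0,74.0
diabetic,0.15,7,69.0,52.5,88.0
diabetic,0.16,12,80.0,51.8,98.5
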