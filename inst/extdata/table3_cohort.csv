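spo2,cohort,sao2_mean,sao2_lo,sao2_hi,bias_mean,bias_hi,bias_lo
89,white,88.5,78,99,0.5,11,-3
90,white,89,80,97.5,1,3,-7.5
91,white,91,83,98,0,8,-7
92,white,92,83.5,98.5,0,8.5,-6.5
93,white,93,85,98,0,8,-5
94,white,93.5,86,98,0.5,8,-4
95,white,94,87,98.5,1,8,-3.5
96,white,94.5,89,99,1.5,7,-3
89,black,86,83,92,3,6,-3
90,black,87,83,97,3,7,-7
91,black,87.5,80,97.5,3.5,11,-6.5
92,black,89,82.5,96,4,9.5,-4
93,black,90,84,97.5,3,7,-7
94,black,91.5,85,97,2.5,9,-3
95,black,92,85.5,97,3,9.5,-2
96,black,92,84,98,4,12,-2
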