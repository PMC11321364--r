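cohort,mean_bias_printed,bias_hi_printed,bias_lo_printed,mean_bias_ratio_printed
white,0.5,7.7,-4.9,6.6
black,3.3,8.9,-4.3,6.6
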