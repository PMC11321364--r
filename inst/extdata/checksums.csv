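name,file,md5
table2_acdc,table2_acdc.csv,ee8d959c80fa376bc274daf70a42fa41
table3_cohort,table3_cohort.csv,520778f206cf859c14793291cf5421d6
table3_summary,table3_summary.csv,b71f5ad9b0de505f2aedbdab25f17c22
calibration_coefficients,calibration_coefficients.csv,64e593b7c92be54322003e0f81a1f3f9
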