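skin,sao2,wavelength,acdc
light,70,660,0.4398
light,75,660,0.3845
light,80,660,0.3232
light,85,660,0.2785
light,90,660,0.2631
light,95,660,0.1610
light,100,660,0.1192
moderate,70,660,0.3012
moderate,75,660,0.2328
moderate,80,660,0.1759
moderate,85,660,0.1524
moderate,90,660,0.2495
moderate,95,660,0.1383
moderate,100,660,0.0831
dark,70,660,0.2114
dark,75,660,0.1758
dark,80,660,0.1607
dark,85,660,0.1316
dark,90,660,0.1085
dark,95,660,0.0811
dark,100,660,0.0586
light,70,940,0.2748
light,75,940,0.2973
light,80,940,0.2949
light,85,940,0.3227
light,90,940,0.3220
light,95,940,0.3007
light,100,940,0.2967
moderate,70,940,0.2340
moderate,75,940,0.2219
moderate,80,940,0.2240
moderate,85,940,0.2247
moderate,90,940,0.3618
moderate,95,940,0.2937
moderate,100,940,0.2543
dark,70,940,0.3051
dark,75,940,0.2305
dark,80,940,0.2258
dark,85,940,0.3015
dark,90,940,0.2425
dark,95,940,0.2296
dark,100,940,0.2585
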