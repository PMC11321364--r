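curve,intercept,slope
commercial,110,-25
light,109,-25.95
moderate,109.2,-32.69
dark,110.6,-50.31
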