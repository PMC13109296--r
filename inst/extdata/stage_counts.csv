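stage,train,val,test
emergence,612,204,204
tillering,716,254,254
jointing,490,163,163
booting,388,112,112
heading,370,121,121
anthesis,284,98,98
filling,366,105,105
maturity,496,184,184
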