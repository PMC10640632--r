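model,component,taken,added,recovery
pls,NZ,4,2,102
pls,NZ,4,4,100.1
pls,NZ,4,8,99.6
pls,PN,10,5,100.3
pls,PN,10,10,100.4
pls,PN,10,20,101.1
ann,NZ,4,2,100.3
ann,NZ,4,4,99.9
ann,NZ,4,8,99
ann,PN,10,5,100.2
ann,PN,10,10,99.3
ann,PN,10,20,100
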