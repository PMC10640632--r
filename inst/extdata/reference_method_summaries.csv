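method,component,mean,sd,n
pls,NZ,99.5,1.82,10
pls,PN,99.8,1.84,10
ann,NZ,100.2,2.12,10
ann,PN,100,1.83,10
reference,NZ,99.6,0.98,5
reference,PN,99.7,1.15,5
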