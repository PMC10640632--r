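component,model,slope,intercept,r,lod,loq,sep,rmsep
NZ,pls,1.0209,-0.1881,0.9989,0.447,1.354,0.161549,0.144494
NZ,ann,1.0046,-0.0224,0.9987,0.494,1.497,0.160227,0.143312
PN,pls,0.9901,0.1796,0.9996,1.75,5.303,0.602116,0.538549
PN,ann,1.0025,0.0281,0.9994,2.093,6.344,0.686162,0.613722
NZ_impB,pls,0.9739,0.0468,0.9994,0.138,0.419,0.056296,0.050353
NZ_impB,ann,0.9959,0.0074,0.9994,0.144,0.435,0.046329,0.041438
PN_impA,pls,1.0245,-0.0763,0.9992,0.454,1.375,0.190702,0.170569
PN_impA,ann,1.001,0.0144,0.9994,0.384,1.163,0.12557,0.112314
PN_impB,pls,0.9925,-0.0112,0.9994,0.389,1.18,0.14163,0.126678
PN_impB,ann,1.0084,-0.0925,0.9997,0.277,0.839,0.106399,0.095166
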