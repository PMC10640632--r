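mix,component,model,actual,recovery
1,NZ,pls,11,102.6
2,NZ,pls,13,100.3
3,NZ,pls,5,99
4,NZ,pls,5,96.5
5,NZ,pls,9,101.2
6,NZ,pls,11,97.8
7,NZ,pls,5,98.3
8,NZ,pls,11,100.5
9,NZ,pls,7,100.6
10,NZ,pls,7,98.4
1,NZ,ann,11,97.4
2,NZ,ann,13,102.9
3,NZ,ann,5,100.8
4,NZ,ann,5,102.9
5,NZ,ann,9,99.3
6,NZ,ann,11,97.4
7,NZ,ann,5,100.2
8,NZ,ann,11,101.7
9,NZ,ann,7,97.9
10,NZ,ann,7,101.5
1,PN,pls,60,98.6
2,PN,pls,10,99.5
3,PN,pls,10,99.1
4,PN,pls,35,97
5,PN,pls,47.5,100.9
6,PN,pls,10,100.7
7,PN,pls,47.5,99.7
8,PN,pls,22.5,98.5
9,PN,pls,22.5,103.9
10,PN,pls,35,100
1,PN,ann,60,98
2,PN,ann,10,98
3,PN,ann,10,97.4
4,PN,ann,35,102.2
5,PN,ann,47.5,102.1
6,PN,ann,10,101.1
7,PN,ann,47.5,101.2
8,PN,ann,22.5,98.9
9,PN,ann,22.5,99.9
10,PN,ann,35,101.4
1,NZ_impB,pls,1,102.4
2,NZ_impB,pls,1,100.8
3,NZ_impB,pls,3,101.4
4,NZ_impB,pls,4,98.5
5,NZ_impB,pls,1,99
6,NZ_impB,pls,4,97.5
7,NZ_impB,pls,2,102.4
8,NZ_impB,pls,2,101.4
9,NZ_impB,pls,3,97.3
10,NZ_impB,pls,1,99.6
1,NZ_impB,ann,1,98.6
2,NZ_impB,ann,1,99.3
3,NZ_impB,ann,3,98.7
4,NZ_impB,ann,4,101
5,NZ_impB,ann,1,100.9
6,NZ_impB,ann,4,97.8
7,NZ_impB,ann,2,99.9
8,NZ_impB,ann,2,100.4
9,NZ_impB,ann,3,102.5
10,NZ_impB,ann,1,100.6
1,PN_impA,pls,2,101.5
2,PN_impA,pls,8,102.2
3,PN_impA,pls,11,102.6
4,PN_impA,pls,2,101.5
5,PN_impA,pls,11,103
6,PN_impA,pls,5,102
7,PN_impA,pls,5,98.6
8,PN_impA,pls,8,97.2
9,PN_impA,pls,2,101.6
10,PN_impA,pls,5,99.9
1,PN_impA,ann,2,97.8
2,PN_impA,ann,8,102.1
3,PN_impA,ann,11,100.2
4,PN_impA,ann,2,100.3
5,PN_impA,ann,11,98.6
6,PN_impA,ann,5,98.3
7,PN_impA,ann,5,98.7
8,PN_impA,ann,8,102.3
9,PN_impA,ann,2,100.9
10,PN_impA,ann,5,103.2
1,PN_impB,pls,8,96.8
2,PN_impB,pls,11,98.7
3,PN_impB,pls,2,102.4
4,PN_impB,pls,11,101.4
5,PN_impB,pls,5,97.6
6,PN_impB,pls,5,99.2
7,PN_impB,pls,8,97.9
8,PN_impB,pls,2,101.5
9,PN_impB,pls,5,99.5
10,PN_impB,pls,2,98.3
1,PN_impB,ann,8,98.4
2,PN_impB,ann,11,99.9
3,PN_impB,ann,2,100
4,PN_impB,ann,11,100.5
5,PN_impB,ann,5,100.3
6,PN_impB,ann,5,96.3
7,PN_impB,ann,8,101.2
8,PN_impB,ann,2,96.3
9,PN_impB,ann,5,97.3
10,PN_impB,ann,2,97.1
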