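variable,stratum,species,beta,se,w
dwat,low,af,-3.76,1.53,8.2
hcov,low,af,-0.64,0.2,4.9
rocks,low,af,0,0,0
con,low,af,0,0,0
tcov,low,af,0,0,0
moist,low,af,0.54,0.32,3.1
scov,low,af,0,0,0
hheight,low,af,0,0,0
logs,low,af,0,0,0
dwat,low,cg,0,0,0
hcov,low,cg,0.38,0.12,2.5
rocks,low,cg,0,0,0
con,low,cg,0.19,0.23,<1
tcov,low,cg,2.98,0.75,69.4
moist,low,cg,-1.07,0.17,4.1
scov,low,cg,0,0,0
hheight,low,cg,0,0,0
logs,low,cg,0.05,0.12,1.2
dwat,high,af,-0.18,0.14,4.2
hcov,high,af,-0.13,0.5,2
rocks,high,af,0.54,0.21,<1
con,high,af,1.4,1.54,1.6
tcov,high,af,-0.72,1.17,1.2
moist,high,af,0.40,0.15,2
scov,high,af,-0.73,0.51,2.1
hheight,high,af,-0.32,0.26,<1
logs,high,af,-0.6,0.36,<1
dwat,high,cg,0.61,0.37,1.3
hcov,high,cg,0,0,0
rocks,high,cg,0.59,0.35,6.3
con,high,cg,1.52,0.52,34.6
tcov,high,cg,0.93,0.35,33.5
moist,high,cg,-0.61,0.36,<1
scov,high,cg,-0.96,0.56,1.9
hheight,high,cg,1.3,0.73,<1
logs,high,cg,0,0,0
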