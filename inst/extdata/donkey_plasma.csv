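analyte,matrix,time_h,conc,n,sd
ABZSO,plasma,0.25,0.11,5,0.02
ABZSO,plasma,0.5,0.23,5,0.04
ABZSO,plasma,1,0.47,5,0.05
ABZSO,plasma,2,0.55,5,0.01
ABZSO,plasma,4,0.78,5,0.14
ABZSO,plasma,6,0.59,5,0.12
ABZSO,plasma,8,0.47,5,0.09
ABZSO,plasma,10,0.41,5,0.07
ABZSO,plasma,12,0.28,5,0.06
ABZSO,plasma,24,0.16,5,0.05
ABZSO,plasma,36,0.11,5,0.04
ABZSO,plasma,48,0.06,5,0.02
ABZSO,plasma,60,0.03,5,0.01
ABZSO,plasma,72,ND,5,
ABZSO2,plasma,0.25,ND,5,
ABZSO2,plasma,0.5,ND,5,
ABZSO2,plasma,1,0.08,5,0.03
ABZSO2,plasma,2,0.26,5,0.07
ABZSO2,plasma,4,0.41,5,0.08
ABZSO2,plasma,6,0.58,5,0.05
ABZSO2,plasma,8,0.37,5,0.06
ABZSO2,plasma,10,0.28,5,0.06
ABZSO2,plasma,12,0.21,5,0.04
ABZSO2,plasma,24,0.15,5,0.04
ABZSO2,plasma,36,0.11,5,0.03
ABZSO2,plasma,48,0.05,5,0.02
ABZSO2,plasma,60,0.03,5,0.01
ABZSO2,plasma,72,ND,5,
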