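analyte,matrix,time_h,conc,n,sd
ABZSO,liver,4,4.93,5,0.98
ABZSO,liver,8,4.26,5,1.05
ABZSO,liver,12,3.56,5,0.87
ABZSO,liver,24,2.98,5,0.85
ABZSO,liver,48,2.22,5,0.73
ABZSO,liver,72,1.67,5,0.36
ABZSO,liver,96,1.32,5,0.27
ABZSO,liver,120,0.23,5,0.08
ABZSO,liver,144,0.10,5,0.04
ABZSO,liver,168,ND,5,
ABZSO,liver,240,ND,5,
ABZSO2,liver,4,2.39,5,0.12
ABZSO2,liver,8,1.49,5,0.33
ABZSO2,liver,12,0.60,5,0.17
ABZSO2,liver,24,0.47,5,0.12
ABZSO2,liver,48,0.38,5,0.09
ABZSO2,liver,72,0.32,5,0.12
ABZSO2,liver,96,0.25,5,0.06
ABZSO2,liver,120,0.17,5,0.05
ABZSO2,liver,144,0.12,5,0.03
ABZSO2,liver,168,0.07,5,0.02
ABZSO2,liver,240,ND,5,
ABZSO2NH2,liver,4,ND,5,
ABZSO2NH2,liver,8,0.14,5,0.05
ABZSO2NH2,liver,12,0.25,5,0.08
ABZSO2NH2,liver,24,0.39,5,0.13
ABZSO2NH2,liver,48,0.49,5,0.15
ABZSO2NH2,liver,72,0.35,5,0.08
ABZSO2NH2,liver,96,0.28,5,0.06
ABZSO2NH2,liver,120,0.18,5,0.04
ABZSO2NH2,liver,144,0.07,5,0.02
ABZSO2NH2,liver,168,0.04,5,0.02
ABZSO2NH2,liver,240,ND,5,
total,liver,4,7.32,5,0.86
total,liver,8,5.89,5,0.68
total,liver,12,4.41,5,0.41
total,liver,24,3.84,5,0.39
total,liver,48,3.09,5,0.43
total,liver,72,2.34,5,0.38
total,liver,96,1.85,5,0.35
total,liver,120,0.58,5,0.29
total,liver,144,0.29,5,0.18
total,liver,168,0.11,5,0.11
total,liver,240,ND,5,
ABZSO,kidney,4,4.84,5,0.56
ABZSO,kidney,8,4.15,5,1.06
ABZSO,kidney,12,3.41,5,0.82
ABZSO,kidney,24,2.65,5,0.09
ABZSO,kidney,48,2.11,5,0.43
ABZSO,kidney,72,1.08,5,0.34
ABZSO,kidney,96,0.69,5,0.17
ABZSO,kidney,120,0.37,5,0.07
ABZSO,kidney,144,0.19,5,0.05
ABZSO,kidney,168,0.08,5,0.03
ABZSO,kidney,240,ND,5,
ABZSO2,kidney,4,0.21,5,0.11
ABZSO2,kidney,8,0.41,5,0.25
ABZSO2,kidney,12,0.34,5,0.74
ABZSO2,kidney,24,0.19,5,0.08
ABZSO2,kidney,48,0.13,5,0.05
ABZSO2,kidney,72,0.07,5,0.02
ABZSO2,kidney,96,0.05,5,0.02
ABZSO2,kidney,120,0.04,5,0.01
ABZSO2,kidney,144,0.02,5,0.01
ABZSO2,kidney,168,ND,5,
ABZSO2,kidney,240,ND,5,
ABZSO2NH2,kidney,4,ND,5,
ABZSO2NH2,kidney,8,0.29,5,0.12
ABZSO2NH2,kidney,12,0.22,5,0.09
ABZSO2NH2,kidney,24,0.18,5,0.11
ABZSO2NH2,kidney,48,0.11,5,0.05
ABZSO2NH2,kidney,72,0.06,5,0.02
ABZSO2NH2,kidney,96,0.04,5,0.02
ABZSO2NH2,kidney,120,ND,5,
ABZSO2NH2,kidney,144,ND,5,
ABZSO2NH2,kidney,168,ND,5,
ABZSO2NH2,kidney,240,ND,5,
total,kidney,4,5.21,5,0.76
total,kidney,8,4.82,5,0.63
total,kidney,12,3.97,5,0.46
total,kidney,24,3.02,5,0.48
total,kidney,48,2.35,5,0.47
total,kidney,72,1.21,5,0.28
total,kidney,96,0.78,5,0.25
total,kidney,120,0.43,5,0.19
total,kidney,144,0.21,5,0.15
total,kidney,168,0.08,5,0.03
total,kidney,240,ND,5,
ABZSO,skin,4,2.89,5,0.65
ABZSO,skin,8,3.49,5,1.25
ABZSO,skin,12,3.17,5,0.57
ABZSO,skin,24,2.80,5,1.24
ABZSO,skin,48,2.51,5,0.72
ABZSO,skin,72,2.09,5,0.46
ABZSO,skin,96,1.83,5,0.47
ABZSO,skin,120,1.69,5,0.36
ABZSO,skin,144,1.10,5,0.28
ABZSO,skin,168,0.62,5,0.14
ABZSO,skin,240,0.09,5,0.03
ABZSO2,skin,4,0.40,5,0.12
ABZSO2,skin,8,0.83,5,0.32
ABZSO2,skin,12,0.66,5,0.17
ABZSO2,skin,24,0.43,5,0.15
ABZSO2,skin,48,0.35,5,0.07
ABZSO2,skin,72,0.29,5,0.08
ABZSO2,skin,96,0.22,5,0.08
ABZSO2,skin,120,0.18,5,0.05
ABZSO2,skin,144,0.13,5,0.04
ABZSO2,skin,168,0.07,5,0.02
ABZSO2,skin,240,ND,5,
ABZSO2NH2,skin,4,ND,5,
ABZSO2NH2,skin,8,ND,5,
ABZSO2NH2,skin,12,ND,5,
ABZSO2NH2,skin,24,ND,5,
ABZSO2NH2,skin,48,ND,5,
ABZSO2NH2,skin,72,ND,5,
ABZSO2NH2,skin,96,ND,5,
ABZSO2NH2,skin,120,ND,5,
ABZSO2NH2,skin,144,ND,5,
ABZSO2NH2,skin,168,ND,5,
ABZSO2NH2,skin,240,ND,5,
total,skin,4,3.29,5,0.58
total,skin,8,4.32,5,0.51
total,skin,12,3.83,5,0.49
total,skin,24,3.23,5,0.47
total,skin,48,2.86,5,0.41
total,skin,72,2.38,5,0.36
total,skin,96,2.05,5,0.42
total,skin,120,1.87,5,0.38
total,skin,144,1.23,5,0.27
total,skin,168,0.69,5,0.26
total,skin,240,0.09,5,0.07
ABZSO,muscle,4,3.89,5,0.54
ABZSO,muscle,8,3.17,5,0.65
ABZSO,muscle,12,2.69,5,0.67
ABZSO,muscle,24,1.84,5,0.45
ABZSO,muscle,48,1.41,5,0.37
ABZSO,muscle,72,0.70,5,0.18
ABZSO,muscle,96,0.25,5,0.06
ABZSO,muscle,120,0.07,5,0.03
ABZSO,muscle,144,ND,5,
ABZSO,muscle,168,ND,5,
ABZSO,muscle,240,ND,5,
ABZSO2,muscle,4,0.94,5,0.24
ABZSO2,muscle,8,0.72,5,0.25
ABZSO2,muscle,12,0.46,5,0.62
ABZSO2,muscle,24,0.31,5,0.15
ABZSO2,muscle,48,0.26,5,0.07
ABZSO2,muscle,72,0.19,5,0.05
ABZSO2,muscle,96,0.12,5,0.04
ABZSO2,muscle,120,0.02,5,0.02
ABZSO2,muscle,144,ND,5,
ABZSO2,muscle,168,ND,5,
ABZSO2,muscle,240,ND,5,
ABZSO2NH2,muscle,4,ND,5,
ABZSO2NH2,muscle,8,ND,5,
ABZSO2NH2,muscle,12,ND,5,
ABZSO2NH2,muscle,24,ND,5,
ABZSO2NH2,muscle,48,ND,5,
ABZSO2NH2,muscle,72,ND,5,
ABZSO2NH2,muscle,96,ND,5,
ABZSO2NH2,muscle,120,ND,5,
ABZSO2NH2,muscle,144,ND,5,
ABZSO2NH2,muscle,168,ND,5,
ABZSO2NH2,muscle,240,ND,5,
total,muscle,4,4.83,5,0.54
total,muscle,8,3.89,5,0.56
total,muscle,12,3.15,5,0.45
total,muscle,24,2.15,5,0.43
total,muscle,48,1.67,5,0.37
total,muscle,72,0.89,5,0.23
total,muscle,96,0.37,5,0.09
total,muscle,120,0.09,5,0.05
total,muscle,144,ND,5,
total,muscle,168,ND,5,
total,muscle,240,ND,5,
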