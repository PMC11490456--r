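code,p_age,p_sex,p_interaction
Sg,0.18,0.26,0.07
G,0.27,0.55,0.14
N,0.57,0.98,0.30
Mn,0.64,0.48,0.42
Rhi,0.30,0.65,0.62
FeL,0.78,0.45,0.86
FeR,0.87,0.64,0.79
SoL,0.87,0.63,0.87
SoR,0.97,0.78,0.88
SkL,0.90,0.67,0.78
SkR,0.69,0.68,0.66
OrL,0.01,0.03,0.00
OrR,0.16,0.27,0.04
SmcL,0.12,0.37,0.14
SmcR,0.08,0.32,0.05
FtL,0.36,0.46,0.10
FtR,0.56,0.66,0.29
FmtL,0.90,0.63,0.78
FmtR,0.86,0.58,0.53
EcL,0.93,0.63,0.94
EcR,0.85,0.99,0.39
MzL,0.04,0.52,0.24
MzR,0.18,0.75,0.20
ZmL,0.33,0.52,0.21
ZmR,0.10,0.04,0.41
JuL,0.41,0.73,0.84
JuR,0.21,0.83,0.47
ZyL,0.17,0.52,0.64
ZyR,0.13,0.38,0.35
CoL,0.30,0.15,0.26
CoR,0.02,0.01,0.14
AlL,0.94,0.70,0.65
AlR,0.43,0.09,0.35
MnmL,0.37,0.41,0.59
MnmR,0.14,0.08,0.36
NmL,0.60,0.52,0.91
NmR,0.52,0.08,0.25
FmoL,0.95,0.64,0.66
FmoR,0.95,0.76,0.37
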