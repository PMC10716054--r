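dinucleotide,twist,tilt,roll,shift,slide,rise
AA,35.5,-1.4,0.5,-0.05,-0.21,3.32
AC,33.1,-0.5,0.5,0.13,-0.54,3.30
AG,30.6,-1.7,4.6,0.09,-0.27,3.38
AT,43.2,0.0,-0.6,0.00,-0.56,3.26
CA,37.7,0.5,4.7,0.09,0.18,3.38
CC,35.3,-0.1,3.6,-0.05,-0.47,3.42
CG,31.3,0.0,5.4,0.00,0.55,3.39
CT,30.6,1.7,4.6,-0.09,-0.27,3.38
GA,39.6,-1.1,1.9,-0.02,-0.03,3.34
GC,38.4,0.0,0.3,0.00,-0.07,3.38
GG,35.3,0.1,3.6,0.05,-0.47,3.42
GT,33.1,0.5,0.5,-0.13,-0.54,3.30
TA,31.6,0.0,3.3,0.00,0.05,3.34
TC,39.6,1.1,1.9,0.02,-0.03,3.34
TG,37.7,-0.5,4.7,-0.09,0.18,3.38
TT,35.5,1.4,0.5,0.05,-0.21,3.32
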