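id,pic50,ha,clogp,le,le_scale,lipe,fq
C1,6.2,25,2.94,0.34,0.36,3.26,0.95
C2,8.1,25,0.81,0.44,0.36,7.29,1.22
C3,8,19,0.27,0.58,0.43,7.73,1.35
C4,5.2,27,1.49,0.26,0.34,3.71,0.76
C5,6,22,4.11,0.37,0.29,1.89,1.28
C6,8,19,3.38,0.58,0.43,4.62,1.35
C7,12.5,26,2.23,0.66,0.35,10.27,1.89
C8,8,25,1.7,0.44,0.36,6.3,1.22
C9,6.4,25,-0.2,0.35,0.36,6.6,0.97
C10,7.2,23,2.5,0.43,0.38,4.7,1.13
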