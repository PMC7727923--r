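case,method,tau,rho
1,ijf,0.07,0.12
2,ijf,0.07,0.86
3,ijf,0.07,0.73
4,ijf,0.07,0.90
5,ijf,0.07,0.87
6,ijf,0.07,0.64
7,ijf,0.07,0.82
8,ijf,0.07,0.79
9,ijf,0.07,0.84
10,ijf,0.07,0.44
11,ijf,0.07,0.83
12,ijf,0.07,0.90
13,ijf,0.07,0.37
14,ijf,0.07,0.25
15,ijf,0.07,0.82
1,mcvc,0.03,0.05
2,mcvc,0.03,0.48
3,mcvc,0.03,0.62
4,mcvc,0.03,0.10
5,mcvc,0.03,0.75
6,mcvc,0.03,0.50
7,mcvc,0.03,0.52
8,mcvc,0.03,0.08
9,mcvc,0.03,0.77
10,mcvc,0.03,0.84
11,mcvc,0.03,-0.06
12,mcvc,0.03,0.33
13,mcvc,0.03,0.20
14,mcvc,0.03,0.06
15,mcvc,0.03,0.54
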