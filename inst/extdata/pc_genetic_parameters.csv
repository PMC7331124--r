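pc,exp_var,h2,se,beta
1,0.29,0.52,0.07,-0.23
2,0.17,0.56,0.08,-1.16
3,0.11,0.68,0.07,0.16
4,0.09,0.67,0.07,0.64
5,0.07,0.50,0.07,-0.25
6,0.04,0.63,0.07,0.19
7,0.02,0.78,0.07,-0.31
8,0.01,0.79,0.07,-0.07
9,0.01,0.68,0.07,-0.03
10,0.01,0.40,0.07,0.10
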