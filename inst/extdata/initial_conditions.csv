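frame,contact,E0,S0
dimensional,0,0.0003,0.0963
dimensional,1,0.0280,0.0109
dimensional,2,0.0399,0.0057
dimensional,6,0.0522,0.0034
nondimensional,0,0.0251,5.0220
nondimensional,0.46,2.7923,0.5712
nondimensional,0.92,3.9869,0.2974
nondimensional,2.76,5.2185,0.1780
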