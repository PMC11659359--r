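name,lo,hi,varied,shifted
alpha1,0.1742,0.2129,TRUE,FALSE
alpha2,0.0772,0.0932,TRUE,TRUE
beta1,5.4315,6.6385,TRUE,FALSE
beta2,0.7470,0.9130,TRUE,FALSE
k0,0.1120,0.1370,TRUE,FALSE
k1,0.0669,0.0829,TRUE,TRUE
k2,0.0360,0.0440,TRUE,FALSE
IC_S,0.0173,0.0211,TRUE,FALSE
IC_E,0.0090,0.0110,TRUE,FALSE
IC_T,3.2760e-6,4.0040e-6,TRUE,FALSE
IC_C,1.9530,2.3870,TRUE,FALSE
n1,,,FALSE,FALSE
n2,,,FALSE,FALSE
n3,,,FALSE,FALSE
n4,,,FALSE,FALSE
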