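name,value,units,varied
alpha1,0.19355,ng/(mL min),TRUE
alpha2,0.080,ng/(mL min),TRUE
beta1,6.035,1/min,TRUE
beta2,0.830,1/min,TRUE
k0,0.1245,ng/(mL min),TRUE
k1,0.080,ng/(mL min),TRUE
k2,0.040,ng/(mL min),TRUE
IC_S,0.01920,ng/mL,TRUE
IC_E,0.010,ng/mL,TRUE
IC_T,3.64e-6,ng/mL,TRUE
IC_C,2.17,cells,TRUE
n1,3,,FALSE
n2,4,,FALSE
n3,2,,FALSE
n4,3,,FALSE
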