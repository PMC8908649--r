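metric,mean_a,mean_b,digits
gamma,1.99,1.91,2
lambda,1.21,1.19,2
sigma,1.59,1.55,2
cp,0.177,0.167,3
lp,3.46,3.65,2
eglob,NA,NA,2
eloc,NA,NA,2
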