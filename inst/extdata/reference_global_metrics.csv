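metric,sparsity,group_a,group_b
gamma,0.05,4.261,3.953
gamma,0.10,2.585,2.453
gamma,0.15,2.013,1.937
gamma,0.20,1.705,1.654
gamma,0.25,1.508,1.467
gamma,0.30,1.376,1.346
gamma,0.35,1.283,1.260
gamma,0.40,1.214,1.194
lambda,0.05,1.541,1.513
lambda,0.10,1.276,1.233
lambda,0.15,1.196,1.172
lambda,0.20,1.165,1.149
lambda,0.25,1.152,1.138
lambda,0.30,1.144,1.132
lambda,0.35,1.140,1.129
lambda,0.40,1.136,1.125
sigma,0.05,2.828,2.710
sigma,0.10,2.055,2.008
sigma,0.15,1.692,1.659
sigma,0.20,1.466,1.442
sigma,0.25,1.311,1.290
sigma,0.30,1.203,1.190
sigma,0.35,1.125,1.117
sigma,0.40,1.068,1.062
cp,0.05,0.184,0.173
cp,0.10,0.198,0.183
cp,0.15,0.193,0.180
cp,0.20,0.184,0.173
cp,0.25,0.175,0.166
cp,0.30,0.168,0.160
cp,0.35,0.162,0.155
cp,0.40,0.157,0.151
lp,0.05,5.820,6.100
lp,0.10,3.742,3.862
lp,0.15,3.246,3.411
lp,0.20,3.068,3.256
lp,0.25,2.990,3.180
lp,0.30,2.953,3.143
lp,0.35,2.935,3.125
lp,0.40,2.926,3.116
eglob,0.05,0.175,0.167
eglob,0.10,0.270,0.262
eglob,0.15,0.311,0.297
eglob,0.20,0.329,0.313
eglob,0.25,0.338,0.321
eglob,0.30,0.342,0.325
eglob,0.35,0.345,0.328
eglob,0.40,0.346,0.329
eloc,0.05,0.385,0.350
eloc,0.10,0.453,0.410
eloc,0.15,0.462,0.424
eloc,0.20,0.456,0.423
eloc,0.25,0.442,0.414
eloc,0.30,0.428,0.402
eloc,0.35,0.416,0.391
eloc,0.40,0.404,0.381
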