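k,ch,c_index,dunn,hartigan,mcclain_rao
10,2142.54026,0.12234,0.00441,0.65763,0.54631
11,2866.86433,0.10477,0.00477,1.05432,0.49791
12,1865.81774,0.12042,0.00463,0.72021,0.55443
13,2836.22720,0.09131,0.00424,1.22610,0.46335
14,3367.74211,0.07645,0.00548,1.47801,0.41643
15,2027.82944,0.10489,0.00424,1.04494,0.51414
16,2603.28507,0.08615,0.00490,1.36384,0.45223
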