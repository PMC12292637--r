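k,ssim,ms_ssim,lpips
10,0.7814,0.2138,0.5008
11,0.7835,0.2130,0.5003
12,0.7801,0.2168,0.5032
13,0.7865,0.2161,0.4987
14,0.7988,0.2196,0.4923
15,0.7889,0.2152,0.4980
16,0.7908,0.2186,0.4939
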