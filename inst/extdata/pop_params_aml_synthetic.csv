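"dose","lambda1","T2","T3","mu_p","mu_pp","mu_deg","Delta"
0,0.385538488396935,1.13289991902958,0.25,0.02,1.5,1.5,0.25
10,0.2,0.6,0.3,0.490054851896175,3,1.5,0.25
100,0.12,0.65,0.35,0.605840412110607,4,1.5,0.25
1000,0.06,0.7,0.4,0.938426877710037,5,1.5,0.25
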