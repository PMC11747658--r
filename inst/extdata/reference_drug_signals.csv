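drug,n_events,ror,ci_low,ci_high,ebgm,ebgm05
atorvastatin,7903,3.94,3.85,4.03,3.75,3.68
fluvastatin,262,8.29,7.29,9.42,7.51,6.75
lovastatin,124,3.39,2.83,4.06,3.28,2.82
pitavastatin,178,3.34,2.87,3.88,3.23,2.85
pravastatin,458,2.25,2.05,2.47,2.21,2.05
rosuvastatin,2512,2.7,2.6,2.81,2.63,2.55
simvastatin,3074,2.88,2.78,2.99,2.8,2.72
all,14511,3.38,3.33,3.44,3.23,3.19
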