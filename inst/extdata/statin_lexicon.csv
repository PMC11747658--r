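canonical,synonym
atorvastatin,ATORVASTATIN
atorvastatin,ATORVASTATIN CALCIUM
atorvastatin,ATORVASTATIN CALCIUM TRIHYDRATE
atorvastatin,LIPITOR
fluvastatin,FLUVASTATIN
fluvastatin,FLUVASTATIN SODIUM
fluvastatin,LESCOL
fluvastatin,LESCOL XL
lovastatin,LOVASTATIN
lovastatin,MEVACOR
lovastatin,ALTOPREV
pitavastatin,PITAVASTATIN
pitavastatin,PITAVASTATIN CALCIUM
pitavastatin,LIVALO
pitavastatin,ZYPITAMAG
pravastatin,PRAVASTATIN
pravastatin,PRAVASTATIN SODIUM
pravastatin,PRAVACHOL
rosuvastatin,ROSUVASTATIN
rosuvastatin,ROSUVASTATIN CALCIUM
rosuvastatin,CRESTOR
rosuvastatin,EZALLOR
simvastatin,SIMVASTATIN
simvastatin,ZOCOR
simvastatin,FLOLIPID
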