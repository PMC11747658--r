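drug,pt,n,ror,ci_low,ci_high,ebgm,ebgm05
atorvastatin,CHOLESTATIC PRURITUS,5,85.3,32.16,226.21,69.08,30.55
atorvastatin,BILIRUBIN CONJUGATED ABNORMAL,9,47.42,23.66,95.03,41.99,23.47
atorvastatin,REYNOLD'S SYNDROME,4,26.05,9.44,71.89,24.35,10.42
atorvastatin,LIVER PALPABLE,9,25.59,13.01,50.32,23.95,13.60
atorvastatin,MIXED LIVER INJURY,133,25.08,21.04,29.91,23.49,20.28
fluvastatin,AUTOIMMUNE HEPATITIS,11,41.6,22.99,75.25,41.34,25.17
fluvastatin,MIXED LIVER INJURY,3,32.09,10.33,99.66,32.01,12.40
fluvastatin,HEPATIC FUNCTION ABNORMAL,36,25.38,18.26,35.27,24.99,18.97
fluvastatin,DRUG-INDUCED LIVER INJURY,19,18.35,11.68,28.82,18.20,12.47
fluvastatin,HEPATOCELLULAR INJURY,12,17,9.64,29.97,16.91,10.52
lovastatin,PORTAL HYPERTENSION,3,22.71,7.31,70.5,22.66,8.78
lovastatin,DRUG-INDUCED LIVER INJURY,15,13.32,8.02,22.14,13.25,8.66
lovastatin,AUTOIMMUNE HEPATITIS,3,10.41,3.35,32.31,10.39,4.03
lovastatin,LIVER INJURY,8,9.15,4.57,18.33,9.13,5.11
lovastatin,HEPATITIS,7,6.4,3.05,13.43,6.38,3.43
pitavastatin,LIVER FUNCTION TEST INCREASED,12,9.92,5.63,17.49,9.89,6.15
pitavastatin,HEPATITIS ACUTE,4,9.8,3.67,26.13,9.78,4.31
pitavastatin,AUTOIMMUNE HEPATITIS,4,9.54,3.58,25.43,9.52,4.19
pitavastatin,ASPARTATE AMINOTRANSFERASE INCREASED,32,9.33,6.59,13.21,9.26,6.92
pitavastatin,GAMMA-GLUTAMYLTRANSFERASE INCREASED,13,8.79,5.1,15.16,8.76,5.55
pravastatin,CHOLESTATIC LIVER INJURY,11,26.4,14.59,47.79,26.20,15.95
pravastatin,MIXED LIVER INJURY,13,23.55,13.65,40.64,23.39,14.81
pravastatin,CHOLESTASIS,47,10.68,8.01,14.22,10.62,8.35
pravastatin,HEPATOCELLULAR INJURY,39,9.31,6.79,12.75,9.26,7.12
pravastatin,HEPATIC CYTOLYSIS,21,7.89,5.14,12.11,7.86,5.49
rosuvastatin,NON-ALCOHOLIC STEATOHEPATITIS,13,10.11,5.85,17.46,9.99,6.32
rosuvastatin,AUTOIMMUNE HEPATITIS,61,8.47,6.58,10.9,8.38,6.79
rosuvastatin,HYPOCOAGULABLE STATE,9,8.43,4.37,16.27,8.36,4.82
rosuvastatin,DRUG-INDUCED LIVER INJURY,237,8.41,7.39,9.56,8.30,7.46
rosuvastatin,LIVER INJURY,172,7.87,6.77,9.15,7.78,6.86
simvastatin,PORTAL FIBROSIS,6,22.84,10.13,51.52,22.14,11.21
simvastatin,NON-ALCOHOLIC FATTY LIVER,8,10.83,5.39,21.78,10.68,5.95
simvastatin,AUTOIMMUNE HEPATITIS,85,10.3,8.32,12.77,10.16,8.49
simvastatin,NON-ALCOHOLIC STEATOHEPATITIS,13,8.78,5.08,15.18,8.68,5.49
simvastatin,HEPATITIS CHOLESTATIC,51,7.04,5.34,9.27,6.97,5.54
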