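pt,scope
DRUG-INDUCED LIVER INJURY,narrow
MIXED LIVER INJURY,narrow
HEPATOCELLULAR INJURY,narrow
CHOLESTATIC LIVER INJURY,narrow
LIVER INJURY,narrow
AUTOIMMUNE HEPATITIS,narrow
HEPATITIS,narrow
HEPATITIS ACUTE,narrow
HEPATITIS CHOLESTATIC,narrow
HEPATITIS FULMINANT,narrow
HEPATITIS TOXIC,narrow
HEPATIC FAILURE,narrow
ACUTE HEPATIC FAILURE,narrow
HEPATIC NECROSIS,narrow
HEPATIC CYTOLYSIS,narrow
CHOLESTASIS,narrow
JAUNDICE,narrow
JAUNDICE CHOLESTATIC,narrow
HEPATIC ENCEPHALOPATHY,narrow
HEPATORENAL SYNDROME,narrow
PORTAL HYPERTENSION,narrow
PORTAL FIBROSIS,narrow
REYNOLD'S SYNDROME,narrow
CHOLESTATIC PRURITUS,narrow
LIVER TRANSPLANT,narrow
DRUG-INDUCED LIVER INJURY,broad
AUTOIMMUNE HEPATITIS,broad
CHOLESTASIS,broad
LIVER INJURY,broad
HEPATITIS,broad
ALANINE AMINOTRANSFERASE INCREASED,broad
ASPARTATE AMINOTRANSFERASE INCREASED,broad
HEPATIC ENZYME INCREASED,broad
GAMMA-GLUTAMYLTRANSFERASE INCREASED,broad
TRANSAMINASES INCREASED,broad
BLOOD BILIRUBIN INCREASED,broad
BILIRUBIN CONJUGATED INCREASED,broad
BILIRUBIN CONJUGATED ABNORMAL,broad
BLOOD ALKALINE PHOSPHATASE INCREASED,broad
LIVER FUNCTION TEST ABNORMAL,broad
LIVER FUNCTION TEST INCREASED,broad
HEPATIC FUNCTION ABNORMAL,broad
HEPATOMEGALY,broad
HEPATIC STEATOSIS,broad
NON-ALCOHOLIC FATTY LIVER,broad
NON-ALCOHOLIC STEATOHEPATITIS,broad
HYPERBILIRUBINAEMIA,broad
OCULAR ICTERUS,broad
LIVER PALPABLE,broad
HEPATIC PAIN,broad
ASCITES,broad
HYPOCOAGULABLE STATE,broad
LIVER DISORDER,broad
HEPATIC CIRRHOSIS,broad
HEPATIC LESION,broad
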