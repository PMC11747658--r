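family,level,drug,count,printed_pct
gender,Female,all,4644,46.0
gender,Male,all,4699,46.5
gender,Unknown,all,753,7.5
age,<18,all,42,0.4
age,18-64.9,all,3352,33.2
age,65-85,all,4358,43.2
age,>85,all,578,5.7
age,Unknown,all,1766,17.5
reporter,Consumer,all,1595,15.8
reporter,Health Professionals,all,1234,12.2
reporter,Lawyer,all,43,0.4
reporter,Physician,all,3470,34.4
reporter,Other health professionals,all,2027,20.1
reporter,Pharmacist,all,1306,12.9
reporter,Registered nurse,all,1,0.0
reporter,Unknown,all,420,4.2
fatality,Fatal outcome,atorvastatin,934,12
fatality,Non-fatal outcome,atorvastatin,6969,88
fatality,Fatal outcome,fluvastatin,39,15
fatality,Non-fatal outcome,fluvastatin,223,85
fatality,Fatal outcome,lovastatin,19,15
fatality,Non-fatal outcome,lovastatin,105,85
fatality,Fatal outcome,pitavastatin,14,8
fatality,Non-fatal outcome,pitavastatin,164,92
fatality,Fatal outcome,pravastatin,48,10
fatality,Non-fatal outcome,pravastatin,410,90
fatality,Fatal outcome,rosuvastatin,325,13
fatality,Non-fatal outcome,rosuvastatin,2187,87
fatality,Fatal outcome,simvastatin,585,19
fatality,Non-fatal outcome,simvastatin,2489,81
fatality,Fatal outcome,all,1964,14
fatality,Non-fatal outcome,all,12547,86
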