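year,atorvastatin,fluvastatin,lovastatin,pitavastatin,pravastatin,rosuvastatin,simvastatin,total,share_pct
2004,93,2,5,,12,5,18,135,1.3
2005,128,6,7,,5,13,25,184,1.8
2006,90,1,5,,2,6,40,144,1.4
2007,24,6,8,,8,7,51,104,1.0
2008,19,2,6,,8,4,64,103,1.0
2009,22,2,7,13,10,8,105,167,1.7
2010,14,11,1,8,6,10,124,174,1.7
2011,28,1,0,,3,5,62,99,1.0
2012,79,7,3,4,21,5,119,238,2.4
2013,61,1,2,4,12,14,160,254,2.5
2014,200,14,7,6,13,52,190,482,4.8
2015,317,15,5,11,18,86,186,638,6.3
2016,346,9,6,12,15,115,167,670,6.6
2017,317,9,1,15,15,99,91,547,5.4
2018,513,9,3,11,41,137,155,869,8.6
2019,772,14,3,11,48,187,151,1186,11.7
2020,687,14,2,4,41,217,188,1153,11.4
2021,576,9,0,6,20,285,74,970,9.6
2022,430,4,3,7,16,253,88,801,7.9
2023,524,27,3,3,13,248,56,874,8.7
2024,207,7,1,1,6,57,25,304,3.0
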