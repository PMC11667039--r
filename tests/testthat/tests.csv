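"analyte","comparison","method","statistic","p_value","n1","n2","significant"
"Ba","BDW_vs_BMW","mann_whitney_u",118,0.818430707416535,15,15,FALSE
"Ba","normality","ks_normality",0.248940817788542,0.0485501026182257,30,NA,TRUE
"Ca","BDW_vs_BMW","mann_whitney_u",77,0.140849421617936,15,15,FALSE
"Ca","normality","ks_normality",0.112593215742505,0.8414302857097,30,NA,FALSE
"Fe","BDW_vs_BMW","mann_whitney_u",112.5,1,15,15,FALSE
"Fe","normality","ks_normality",0.534491724892716,7.19181580528159e-08,30,NA,TRUE
"K","BDW_vs_BMW","mann_whitney_u",108,0.85168923677707,15,15,FALSE
"K","normality","ks_normality",0.218105728611839,0.115180998630533,30,NA,FALSE
"Li","BDW_vs_BMW","mann_whitney_u",91,0.365979943229129,15,15,FALSE
"Li","normality","ks_normality",0.196084005517894,0.198935115177142,30,NA,FALSE
"Mg","BDW_vs_BMW","mann_whitney_u",143.5,0.198405982277797,15,15,FALSE
"Mg","normality","ks_normality",0.0898552265239949,0.968740585329602,30,NA,FALSE
"Mn","BDW_vs_BMW","mann_whitney_u",135,0.0731157655675006,15,15,FALSE
"Mn","normality","ks_normality",0.510483345533713,3.2402421591209e-07,30,NA,TRUE
"Na","BDW_vs_BMW","mann_whitney_u",194,0.000723639424324734,15,15,TRUE
"Na","normality","ks_normality",0.243775853981739,0.0565587444628645,30,NA,FALSE
"nitrate","BDW_vs_BMW","mann_whitney_u",573.5,0.067853573735205,30,30,FALSE
"nitrate","summer_vs_winter","kruskal_wallis",0.238059245262042,0.62561135730897,30,30,FALSE
"nitrate","normality","ks_normality",0.220495450209817,0.00585158875784144,60,NA,TRUE
"nitrite","BDW_vs_BMW","mann_whitney_u",604.5,0.0187741266941383,30,30,TRUE
"nitrite","summer_vs_winter","kruskal_wallis",16.6166357870384,4.57479874769731e-05,30,30,TRUE
"nitrite","normality","ks_normality",0.337285422124007,2.35674875079492e-06,60,NA,TRUE
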