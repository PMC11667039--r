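"water_type","analyte","n_total","n_detected","detection_rate","n_used","mean_detected","min_detected","max","min_below_lod","unit"
"BDW","Na",15,15,1,15,12.322,0.93,23.32,FALSE,"mg/L"
"BDW","Ca",15,15,1,15,7.87533333333333,0.05,17.18,FALSE,"mg/L"
"BDW","nitrate",30,30,1,30,7.63133333333333,0.28,38.87,FALSE,"mg/L"
"BDW","Mg",15,15,1,15,4.96066666666667,0.67,8.87,FALSE,"mg/L"
"BDW","K",15,15,1,15,0.122,0.02,0.23,FALSE,"mg/L"
"BDW","nitrite",30,22,0.733333333333333,22,0.0295909090909091,0.001,0.13,TRUE,"mg/L"
"BDW","Ba",15,13,0.866666666666667,13,11.3023076923077,0.9,58.6,TRUE,"ug/L"
"BDW","Li",15,11,0.733333333333333,10,2.52,0,5.7,FALSE,"ug/L"
"BDW","Fe",15,2,0.133333333333333,1,1.4,0,1.4,FALSE,"ug/L"
"BDW","Mn",15,3,0.2,3,0.22,0.1,0.36,TRUE,"ug/L"
"BDW","Be",15,0,0,0,NA,NA,0.042,TRUE,"ug/L"
"BDW","Mo",15,0,0,0,NA,NA,1.666,TRUE,"ug/L"
"BMW","Ca",15,15,1,15,12.262,3.28,25.95,FALSE,"mg/L"
"BMW","nitrate",30,29,0.966666666666667,29,4.13758620689655,0.48,10.75,TRUE,"mg/L"
"BMW","Mg",15,15,1,15,3.74933333333333,1.24,9.34,FALSE,"mg/L"
"BMW","Na",15,15,1,15,3.15666666666667,0.55,12.32,FALSE,"mg/L"
"BMW","K",15,15,1,15,0.17,0.04,0.37,FALSE,"mg/L"
"BMW","Ba",15,10,0.666666666666667,10,15.71,0.49,55.9,TRUE,"ug/L"
"BMW","nitrite",30,17,0.566666666666667,17,0.00952941176470588,0.001,0.04,TRUE,"mg/L"
"BMW","Li",15,10,0.666666666666667,10,4.127,1.1,6.42,TRUE,"ug/L"
"BMW","Be",15,0,0,0,NA,NA,0.042,TRUE,"ug/L"
"BMW","Fe",15,0,0,0,NA,NA,0.16,TRUE,"ug/L"
"BMW","Mn",15,0,0,0,NA,NA,0.066,TRUE,"ug/L"
"BMW","Mo",15,0,0,0,NA,NA,1.666,TRUE,"ug/L"
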