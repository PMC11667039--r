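"analyte","group","n_iter","seed","rfd","mean_hq","flagged","cdi_p5","hq_p5","cdi_p50","hq_p50","cdi_p95","hq_p95"
"nitrate","children",10000,2,1.6,0.247209791666667,FALSE,0.032,0.02,0.27,0.16875,1.35066666666667,0.844166666666667
"nitrate","adults",10000,3,1.6,0.102578267857143,FALSE,0.0128571428571429,0.00803571428571428,0.114285714285714,0.0714285714285714,0.578857142857143,0.361785714285714
"nitrite","children",10000,4,0.1,0.00907066666666667,FALSE,3.33333333333333e-05,0.000333333333333333,6.66666666666667e-05,0.000666666666666667,0.00466666666666667,0.0466666666666667
"nitrite","adults",10000,5,0.1,0.00388314285714286,FALSE,1.42857142857143e-05,0.000142857142857143,2.85714285714286e-05,0.000285714285714286,0.002,0.02
"Ba","children",10000,6,0.2,0.00337049313333333,FALSE,3.26666666666667e-06,1.63333333333333e-05,0.00038,0.0019,0.00372666666666667,0.0186333333333333
"Ba","adults",10000,7,0.2,0.00147851741428571,FALSE,1.4e-06,7e-06,0.000162857142857143,0.000814285714285714,0.00159714285714286,0.00798571428571429
"Fe","children",10000,8,0.7,1.15744761904762e-05,FALSE,5.33333333333333e-06,7.61904761904762e-06,5.33333333333333e-06,7.61904761904762e-06,5.33333333333333e-06,7.61904761904762e-06
"Fe","adults",10000,9,0.7,4.9425306122449e-06,FALSE,2.28571428571429e-06,3.26530612244898e-06,2.28571428571429e-06,3.26530612244898e-06,2.28571428571429e-06,3.26530612244898e-06
"Li","children",10000,10,0.028,0.0053259719047619,FALSE,1.33333333333333e-07,4.76190476190476e-06,1e-04,0.00357142857142857,0.000425333333333333,0.0151904761904762
"Li","adults",10000,11,0.028,0.00227775102040816,FALSE,5.71428571428571e-08,2.04081632653061e-06,3.71428571428571e-05,0.0013265306122449,0.000182285714285714,0.00651020408163265
"Mn","children",10000,12,0.14,2.4678e-05,FALSE,2.2e-06,1.57142857142857e-05,2.2e-06,1.57142857142857e-05,1.33333333333333e-05,9.52380952380952e-05
"Mn","adults",10000,13,0.14,1.07298367346939e-05,FALSE,9.42857142857143e-07,6.73469387755102e-06,9.42857142857143e-07,6.73469387755102e-06,5.71428571428571e-06,4.08163265306122e-05
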