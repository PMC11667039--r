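"brand","season","analyte","measured","limit","source","exceeds","label_qualifier"
"BDW1","pooled","nitrate",6.91,2.4,"label",TRUE,"exact"
"BDW4","pooled","nitrate",4.13,3.5,"label",TRUE,"exact"
"BDW5","pooled","nitrate",1.34,1,"label",TRUE,"less_than"
"BDW6","pooled","nitrate",8.42,0.4,"label",TRUE,"exact"
"BDW7","pooled","nitrate",5.32,2,"label",TRUE,"less_than"
"BDW9","pooled","nitrate",5.78,2.3,"label",TRUE,"exact"
"BDW11","pooled","nitrate",1.4,1.3,"label",TRUE,"exact"
"BDW12","pooled","nitrate",6.04,1,"label",TRUE,"exact"
"BDW13","pooled","nitrate",4.89,2.3,"label",TRUE,"exact"
"BDW14","pooled","nitrate",20.26,15,"label",TRUE,"exact"
"BDW15","pooled","nitrate",5.81,0,"label",TRUE,"exact"
"BMW2","pooled","nitrate",3.58,0.8,"label",TRUE,"less_than"
"BMW4","pooled","nitrate",4.77,2,"label",TRUE,"exact"
"BMW7","pooled","nitrate",9.07,2.88,"label",TRUE,"exact"
"BMW8","pooled","nitrate",9.77,0.005,"label",TRUE,"exact"
"BMW10","pooled","nitrate",3.86,0.9,"label",TRUE,"exact"
"BMW11","pooled","nitrate",2.59,0.7,"label",TRUE,"exact"
"BMW12","pooled","nitrate",2.98,0.7,"label",TRUE,"exact"
"BMW13","pooled","nitrate",4.05,0.8,"label",TRUE,"exact"
"BMW14","pooled","nitrate",5.32,5,"label",TRUE,"exact"
"BMW15","pooled","nitrate",2.39,0.5,"label",TRUE,"exact"
"BDW4","pooled","nitrite",0.04,0.01,"label",TRUE,"exact"
"BDW6","pooled","nitrite",0.08,0,"label",TRUE,"exact"
"BDW7","pooled","nitrite",0.03,0,"label",TRUE,"exact"
"BDW10","pooled","nitrite",0.04,0.01,"label",TRUE,"exact"
"BDW11","pooled","nitrite",0.03,0.005,"label",TRUE,"exact"
"BDW12","pooled","nitrite",0.02,0,"label",TRUE,"exact"
"BDW13","pooled","nitrite",0.13,0.05,"label",TRUE,"less_than"
"BDW14","pooled","nitrite",0.05,0,"label",TRUE,"exact"
"BDW15","pooled","nitrite",0.04,0,"label",TRUE,"exact"
"BMW2","pooled","nitrite",0.02,0.004,"label",TRUE,"less_than"
"BMW3","pooled","nitrite",0.02,0.014,"label",TRUE,"exact"
"BMW4","pooled","nitrite",0.02,0.01,"label",TRUE,"exact"
"BMW8","pooled","nitrite",0.04,0.003,"label",TRUE,"exact"
"BMW10","pooled","nitrite",0.001,0,"label",TRUE,"exact"
"BMW14","pooled","nitrite",0.01,0,"label",TRUE,"exact"
"BMW15","pooled","nitrite",0.01,0,"label",TRUE,"exact"
"BDW1","pooled","Mg",8.87,2.5,"label",TRUE,"exact"
"BDW9","pooled","Mg",4.47,4.3,"label",TRUE,"exact"
"BDW15","pooled","Mg",2.96,1.5,"label",TRUE,"exact"
"BMW4","pooled","Mg",6.77,6.25,"label",TRUE,"exact"
"BMW12","pooled","Mg",5.52,0,"label",TRUE,"exact"
"BMW15","pooled","Mg",1.25,0.3,"label",TRUE,"exact"
"BDW1","pooled","Na",3.68,1.3,"label",TRUE,"exact"
"BDW2","pooled","Na",22.18,12,"label",TRUE,"exact"
"BDW6","pooled","Na",2.85,1,"label",TRUE,"exact"
"BDW7","pooled","Na",10.89,9,"label",TRUE,"exact"
"BDW9","pooled","Na",21.18,16.7,"label",TRUE,"exact"
"BDW10","pooled","Na",23.32,10.7,"label",TRUE,"exact"
"BDW12","pooled","Na",17.92,8,"label",TRUE,"exact"
"BDW13","pooled","Na",19.34,16.7,"label",TRUE,"exact"
"BMW7","pooled","Na",12.32,11,"label",TRUE,"exact"
"BMW13","pooled","Na",4.99,4.41,"label",TRUE,"exact"
"BMW14","pooled","Na",1.06,0.51,"label",TRUE,"exact"
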