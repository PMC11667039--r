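"analyte","n_labeled","n_exceeding","fraction"
"nitrate",26,21,0.807692307692308
"nitrite",20,16,0.8
"Ca",30,0,0
"K",11,0,0
"Mg",29,6,0.206896551724138
"Na",26,11,0.423076923076923
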