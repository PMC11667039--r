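"brand","season","analyte","measured","limit","source","exceeds"
"BDW13","summer","nitrite",0.13,0.1,"INSO",TRUE
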