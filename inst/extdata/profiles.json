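{
  "children": {"ir": 1, "ef": 365, "ed": 4,  "bw": 15, "at": 1460},
  "adults":   {"ir": 2, "ef": 365, "ed": 40, "bw": 70, "at": 14600}
}
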