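aquarisk pipeline report
========================
records in: 420 (153 censored)
summary: 24 analyte x group rows
compliance INSO: 1 violation(s)
compliance WHO: 0 violation(s)
label findings: 54 over 142 labelled comparisons
rank tests: 22 comparisons, 8 significant at 0.05
risk: 12 analyte x group rows, 0 with HQ above 1
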