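"id","urine_creatinine"
"S0001",117.3
"S0002",74.5
"S0003",125
"S0004",155.3
"S0005",86.1
"S0006",62.1
"S0007",162.8
"S0008",127.2
"S0009",82.4
"S0010",117.8
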