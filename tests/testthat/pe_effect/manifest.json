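{
  "subcommand": "depe",
  "package": "patternEffect 0.1.0",
  "both_strands": false,
  "correction": "bonferroni",
  "seed": 1,
  "out": "pe_effect",
  "class1": "a",
  "class2": "a",
  "one_vs_rest": false,
  "help": false
}
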