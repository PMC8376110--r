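{
  "subcommand": "train",
  "package": "patternEffect 0.1.0",
  "out": "pe_train",
  "val_chroms": "chr18",
  "test_chroms": "chr19",
  "epochs": 5,
  "ensemble_size": 5,
  "first_filters": 64,
  "first_width": 17,
  "seed": 1,
  "help": false
}
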