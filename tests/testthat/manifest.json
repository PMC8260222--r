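{
  "package": "esmscreen",
  "version": "0.1.0",
  "r_version": "R version 4.3.3 (2024-02-29)",
  "timestamp": "2026-09-30T02:53:12+0000",
  "params": {
    "subcommand": "screen-corr",
    "expression": true
  },
  "input_md5": {}
}
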