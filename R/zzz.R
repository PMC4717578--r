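.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", "code", "pos", "n", "p1", "p2", "d", "qpos", "spos",
  "diag", "chain", "spos2"
))
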