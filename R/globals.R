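utils::globalVariables(c("gid", "g", "q", "bin_lo", "bin_hi", "offset",
                         "expression_class", "num", "den", "side", "w"))
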