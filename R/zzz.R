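# non-standard-evaluation column names used in plotting / aggregation
utils::globalVariables(c(
  "o", "sp", "o_lo", "o_hi", "sp_lo", "sp_hi", "process",
  "x", "y", "xend", "yend", "line", "d18o", "sigma_sp", "sigma_d18o",
  "f_bd", "r_n2o", "scenario"
))
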