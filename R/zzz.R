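.datatable.aware <- TRUE

utils::globalVariables(c(
  ".t", ".bout", "tag_code", "antenna_id", "timestamp", "start", "end",
  "V1", "overlap_s", "zero_dur", "bin_start", "bin_i", "bs", "s", "e",
  "i0", "i1", "presence", "eggs", "alloc", "total_s", "n_zero", "bleak",
  "temp_c", "period", "date", "year", "bleak_id", "tot", "night", "g", "v",
  "w", "day_s", "tot_s"))
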