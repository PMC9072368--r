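## data.table NSE columns referenced inside this package
utils::globalVariables(c(
  ".", "c_all", "c_count", "c_hq", "c_pf", "cov_hq", "cov_pf", "coverage",
  "bad", "conversion_rate", "converted", "db", "fail1", "fail2",
  "first_fail", "gene_id", "informative", "level", "level_pf",
  "level_rep1", "level_rep2", "low_confidence", "n_C", "n_T",
  "n_motif_G", "motif_pos", "nonconv", "obs", "p_rep1", "p_rep2",
  "p_value", "planted_type", "pos", "qual", "read_id", "resistant",
  "rid", "rl", "signal_ratio", "species", "start", "state", "t_all",
  "t_hq", "t_pf", "tid", "tidA", "tidB", "posA", "posB", "transcript_id",
  "true_level", "unconverted", "variant_id", "combined_p", "site_id",
  "i.lvl", "i.bad"))
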