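# Small in-code fixtures shared across test files.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_studies = 3, n_genes = 100, n_proteins = 30, n_metabolites = 20,
         n_neg = 10, n_pos = 12, frac_diff = 0.2, effect_size = 1.5,
         panel_overlap = 1, missing_rate = 0.1, seed = 11L),
    list(...))
  do.call(sim_config, args)
}

# a labeled matrix with known values: 2 ERneg and 2 ERpos samples
toy_matrix <- function(values, platform = "metabolite") {
  omics_matrix(values, rep(c("ERneg", "ERpos"), each = ncol(values) / 2),
               platform)
}

make_diff_table <- function(feature_id, raw_p, fold_change,
                            study_id = "s1", platform = "transcript") {
  structure(
    data.frame(feature_id = feature_id, raw_p = raw_p,
               fold_change = fold_change,
               direction = ifelse(fold_change > 1, "up",
                                  ifelse(fold_change < 1, "down",
                                         "unchanged")),
               test = "fixture", n_neg = 10L, n_pos = 10L,
               stringsAsFactors = FALSE),
    study_id = study_id, platform = platform,
    class = c("diff_table", "data.frame"))
}
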