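# Shared fixture builders: simulated cohorts at desk scale, and the
# end-to-end no-noise recovery experiment reused by property and
# acceptance tests.

# `per_clone` samples for each clone, high purity, plus a matched normal;
# two samples per clone reproduces the study condition that every clone is
# carried by several samples (required for recall through the
# confident-site filter)
clean_cohort_specs <- function(n_clones, purity = 1, depth = 200,
                               per_clone = 1) {
  clone <- rep(seq_len(n_clones), each = per_clone)
  suffix <- if (per_clone > 1) rep(letters[seq_len(per_clone)], n_clones) else ""
  grp <- rep(c("primary", "ascites"), length.out = n_clones)
  specs <- sample_specs(
    sample_id = paste0("S", clone, suffix),
    group = grp[clone],
    clone_id = paste0("C", clone),
    purity = rep(purity, length(clone)),
    mean_depth = rep(depth, length(clone)))
  rbind(specs, sample_specs("normal", "normal", "normal", 0, depth))
}

# run simulate -> consensus for a cohort; returns consensus + wes + specs
run_snv_chain <- function(tree, specs, error = error_model(), seed = 1L,
                          config = consensus_config()) {
  wes <- lapply(seq_len(nrow(specs)), function(i)
    simulate_pileups_and_callsets(specs[i, ], tree, error = error, seed = seed))
  names(wes) <- specs$sample_id
  tumor <- specs$sample_id[specs$group != "normal"]
  calls <- do.call(rbind, lapply(wes[tumor], `[[`, "callsets"))
  groups <- stats::setNames(specs$group, specs$sample_id)
  cons <- build_consensus_table(calls, lapply(wes, `[[`, "pileup"),
                                NULL, groups, config = config)
  list(consensus = cons, wes = wes, calls = calls, specs = specs,
       tumor = tumor)
}

# end-to-end no-noise recovery: returns RF(found, truth) for SNV and CNA trees
recovery_replicate <- function(seed, n_clones = 6, n_snvs = 60, n_cnas = 12,
                               n_bins = 400, n_positions = 5e4) {
  g <- synthetic_genome(scale = 0.01)
  tree <- simulate_clone_tree(n_clones, n_snvs, n_cnas, g, seed = seed)
  specs <- clean_cohort_specs(n_clones)
  truth <- true_sample_tree(tree, specs)
  tumor <- specs$sample_id[specs$group != "normal"]

  chain <- run_snv_chain(tree, specs, error_model(), seed = seed)
  snv_mat <- binary_snv_matrix(chain$consensus, include_samples = tumor)
  mp_snv <- search_max_parsimony(snv_mat)
  rf_snv <- compare_trees(mp_snv$consensus, truth)

  set.seed(substream_seed(seed, "recovery_reference"))
  ci <- sample.int(nrow(g), n_positions, replace = TRUE,
                   prob = g$length / sum(g$length))
  ref_pos <- data.frame(chrom = g$chrom[ci],
                        pos = floor(stats::runif(n_positions) * g$length[ci]))
  bins <- build_variable_bins(ref_pos, n_bins = n_bins, genome = g,
                              gc_fun = synthetic_gc_fun(g))
  cnt <- sapply(seq_len(nrow(specs)), function(i)
    simulate_binned_counts(specs[i, ], tree, bins, linear_gc_bias, seed = seed))
  colnames(cnt) <- specs$sample_id
  nrm <- apply(cnt, 2, lowess_gc_normalize, gc_per_bin = bins$gc_fraction)
  rat <- t(apply(nrm, 2, function(x)
    estimate_copy_ratio(x, nrm[, "normal"])$ratio))
  rownames(rat) <- specs$sample_id
  seg <- joint_segmentation(rat, bins, gamma = 50)
  cna_mat <- trinary_matrix(seg)
  mp_cna <- search_max_parsimony(cna_mat)
  rf_cna <- compare_trees(mp_cna$consensus, truth)

  list(rf_snv = rf_snv, rf_cna = rf_cna, tree = tree, truth = truth,
       consensus = chain$consensus)
}
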