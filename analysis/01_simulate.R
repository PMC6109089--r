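#!/usr/bin/env Rscript

# Stage 1: simulate the study cohort.
#
# A clone tree (ancestral clone -> primary-tissue clone + ascites clone)
# with branch-assigned CNAs and SNVs; five multi-region primary samples,
# five ascites spheroids (two dominated by normal cells) and a matched
# normal. Writes the ground truth and all "sequencing-like" observations:
# binned whole-genome read counts, per-locus pileups, and three caller
# call sets per sample as VCF.

suppressMessages(library(spherophylo))

cfg <- default_config(seed = 1L)
out <- "results/data"
dir.create(file.path(out, "vcf"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "pileup"), showWarnings = FALSE)

genome <- synthetic_genome(scale = cfg$genome_scale)
tree <- simulate_clone_tree(cfg$n_clones, cfg$n_snvs, cfg$n_cnas, genome,
                            seed = cfg$seed, parents = cfg$clone_parents)
specs <- cfg$samples
message("simulated ", cfg$n_clones, " clones, ", nrow(tree$snvs), " SNVs, ",
        nrow(tree$cnas), " CNAs; ", nrow(specs) - 1L, " tumor samples + normal")

write.table(genome, file.path(out, "genome.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(specs, file.path(out, "samples.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_truth_tsv(tree, file.path(out, "truth_events.tsv"))
write_newick(true_sample_tree(tree, specs), file.path(out, "truth_tree.nwk"))

# binned WGS counts on variable-size bins built from a synthetic
# uniquely-mappable reference
set.seed(substream_seed(cfg$seed, "reference_positions"))
npos <- cfg$n_reference_positions
ci <- sample.int(nrow(genome), npos, replace = TRUE,
                 prob = genome$length / sum(genome$length))
ref_pos <- data.frame(chrom = genome$chrom[ci],
                      pos = floor(runif(npos) * genome$length[ci]))
bins <- build_variable_bins(ref_pos, n_bins = cfg$n_bins, genome = genome,
                            gc_fun = synthetic_gc_fun(genome))
counts <- sapply(seq_len(nrow(specs)), function(i) {
  spec <- specs[i, ]
  spec$mean_depth <- cfg$wgs_reads_per_bin
  simulate_binned_counts(spec, tree, bins, gc_bias = linear_gc_bias,
                         seed = cfg$seed)
})
colnames(counts) <- specs$sample_id
write_bed_bins(cbind(bins, counts), file.path(out, "bins_counts.tsv"))
message("wrote ", cfg$n_bins, " bins x ", ncol(counts), " samples of WGS counts")

# WES pileups and three caller call sets per sample, with germline SNPs
# shared by every sample including the matched normal
germline <- simulate_germline_loci(cfg$n_germline, genome, tree, cfg$seed)
for (i in seq_len(nrow(specs))) {
  s <- specs$sample_id[i]
  sim <- simulate_pileups_and_callsets(specs[i, ], tree, error = cfg$error,
                                       seed = cfg$seed,
                                       extra_het_loci = germline)
  write_pileup_tsv(sim$pileup, file.path(out, "pileup", paste0(s, ".tsv")))
  for (caller in unique(sim$callsets$caller_id)) {
    cs <- sim$callsets[sim$callsets$caller_id == caller, ]
    write_vcf(cs, file.path(out, "vcf", paste0(s, ".", caller, ".vcf")),
              sample_id = s)
  }
}
message("wrote pileups and per-caller VCFs under ", out)
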