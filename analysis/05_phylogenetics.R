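#!/usr/bin/env Rscript

# Stage 5: event matrices and maximum-parsimony phylogenies.
#
# Jointly segments the copy-number ratio profiles with shared breakpoints
# (gamma = 50), builds the trinary CNA matrix (+/-0.7 event, +/-0.5 neutral
# thresholds around each sample's mean ploidy) and the binary SNV matrix,
# searches for maximum-parsimony trees with the normal as outgroup, and
# compares the two tree topologies (and each against the simulated truth).

suppressMessages(library(spherophylo))

cfg <- default_config(seed = 1L)
out <- "results/phylo"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

specs <- read.table("results/data/samples.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
tumor <- specs$sample_id[specs$group != "normal"]
normal_id <- specs$sample_id[specs$group == "normal"][1]
purity <- read.table("results/vaf/purity.tsv", header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
included <- purity$sample_id[!purity$low_purity]
message("included samples (purity >= ", cfg$low_purity_threshold, "): ",
        paste(included, collapse = ", "))

rt <- read_bed_bins("results/cna/ratios.tsv")
bins <- rt[, c("chrom", "start", "end")]
ratios <- t(as.matrix(rt[, c(included, normal_id)]))
rownames(ratios)[nrow(ratios)] <- "normal"
seg <- joint_segmentation(ratios, bins, gamma = cfg$gamma)
message("joint segmentation: ", nrow(seg$segments), " segments (",
        seg$n_breakpoints, " shared breakpoints)")
cna_mat <- trinary_matrix(seg, event_delta = cfg$event_delta,
                          neutral_delta = cfg$neutral_delta)

cons_tab <- read.table("results/snv/consensus.tsv", header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
presence <- as.matrix(cons_tab[, tumor]) == 1
rownames(presence) <- paste(cons_tab$chrom, cons_tab$pos, cons_tab$alt,
                            sep = ":")
cons <- structure(list(
  loci = cons_tab[, c("chrom", "pos", "ref", "alt", "category")],
  presence = presence), class = "consensus_table")
snv_mat <- binary_snv_matrix(cons, include_samples = included)

cna_tree <- search_max_parsimony(cna_mat, seed = cfg$seed)
snv_tree <- search_max_parsimony(snv_mat, seed = cfg$seed)
rf <- compare_trees(cna_tree, snv_tree)
message("CNA tree: parsimony score ", cna_tree$score,
        "; SNV tree: parsimony score ", snv_tree$score)
message("RF(CNA tree, SNV tree) = ", rf)

truth <- read_newick("results/data/truth_tree.nwk")
truth_inc <- ape::keep.tip(truth, intersect(truth$tip.label,
                                            c(included, "normal")))
message("RF(SNV tree, simulated truth) = ",
        compare_trees(snv_tree$consensus, truth_inc))
message("RF(CNA tree, simulated truth) = ",
        compare_trees(cna_tree$consensus, truth_inc))

write.table(cbind(attr(cna_mat, "characters"), t(cna_mat)),
            file.path(out, "cna_matrix.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cbind(attr(snv_mat, "characters"), t(snv_mat)),
            file.path(out, "snv_matrix.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_newick(cna_tree, file.path(out, "cna_tree.nwk"))
write_newick(snv_tree, file.path(out, "snv_tree.nwk"))
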