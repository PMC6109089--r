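#!/usr/bin/env Rscript

# Stage 4: VAF distributions, tumor purity, and clonality.
#
# Computes per-sample VAFs at the consensus loci, estimates purity as twice
# the median clonal VAF (flagging normal-cell-dominated spheroids for
# exclusion), tests common-vs-private VAF shifts (subclonal structure), and
# computes the pairwise clonality index.

suppressMessages(library(spherophylo))

cfg <- default_config(seed = 1L)
dat <- "results/data"
out <- "results/vaf"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

specs <- read.table(file.path(dat, "samples.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
tumor <- specs$sample_id[specs$group != "normal"]
cons_tab <- read.table("results/snv/consensus.tsv", header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
loci <- cons_tab[, c("chrom", "pos", "ref", "alt", "category")]
presence <- as.matrix(cons_tab[, tumor]) == 1
rownames(presence) <- paste(loci$chrom, loci$pos, loci$alt, sep = ":")
cons <- structure(list(loci = loci, presence = presence), class = "consensus_table")
pileups <- lapply(tumor, function(s)
  read_pileup_tsv(file.path(dat, "pileup", paste0(s, ".tsv"))))
names(pileups) <- tumor

vafs <- compute_vafs(cons, pileups)
purity <- do.call(rbind, lapply(tumor, function(s)
  as.data.frame(estimate_purity(vafs[vafs$sample_id == s, ], sample_id = s,
                                low_purity_threshold = cfg$low_purity_threshold))))
tests <- do.call(rbind, lapply(tumor, function(s) {
  r <- compare_common_vs_private(vafs[vafs$sample_id == s, ],
                                 group = specs$group[specs$sample_id == s],
                                 alpha = cfg$vaf_alpha)
  data.frame(sample_id = s, p_value = r$p_value, verdict = r$verdict)
}))

included <- purity$sample_id[!purity$low_purity]
pairs <- combn(included, 2)
clonality <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
  a <- pairs[1, j]; b <- pairs[2, j]
  ci <- clonality_index(rownames(presence)[presence[, a]],
                        rownames(presence)[presence[, b]],
                        background_prob = cfg$background_prob)
  data.frame(sample_a = a, sample_b = b, ci = round(ci$ci, 3),
             n_shared = ci$n_shared)
}))

message("purity estimates:")
for (i in seq_len(nrow(purity)))
  message(sprintf("  %-6s %.2f%s", purity$sample_id[i], purity$purity[i],
                  if (purity$low_purity[i]) "  [low purity - excluded]" else ""))
message(sum(tests$verdict == "subclonal structure"), " of ", nrow(tests),
        " samples show higher common than group-private VAFs (subclonal structure)")
lo_hi <- c("LO", grep("^RO", included, value = TRUE)[1])
if (all(lo_hi %in% included)) {
  ci_lr <- clonality$ci[clonality$sample_a %in% lo_hi &
                        clonality$sample_b %in% lo_hi]
  message("clonality index, left vs right ovary samples: CI = ",
          format(round(ci_lr, 1), nsmall = 1))
}

write.table(vafs, file.path(out, "vafs.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(purity, file.path(out, "purity.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(tests, file.path(out, "vaf_tests.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(clonality, file.path(out, "clonality.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
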