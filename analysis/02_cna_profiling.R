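#!/usr/bin/env Rscript

# Stage 2: copy-number profiling.
#
# Reads the binned WGS counts, applies Lowess GC normalization, scales each
# sample by the median depth of the matched normal (reference DNA) to get
# copy-number ratios, runs depth-distribution QC, and clusters the profiles
# into genetic subgroups.

suppressMessages(library(spherophylo))

cfg <- default_config(seed = 1L)
dat <- "results/data"
out <- "results/cna"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_bed_bins(file.path(dat, "bins_counts.tsv"))
specs <- read.table(file.path(dat, "samples.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
bin_cols <- c("chrom", "start", "end", "gc_fraction", "expected_reads")
bins <- tab[, bin_cols]
counts <- as.matrix(tab[, specs$sample_id])
normal_id <- specs$sample_id[specs$group == "normal"][1]

norm <- apply(counts, 2, lowess_gc_normalize, gc_per_bin = bins$gc_fraction,
              lowess_fraction = cfg$lowess_fraction)
ratios <- sapply(specs$sample_id, function(s)
  estimate_copy_ratio(norm[, s], norm[, normal_id], sample_id = s)$ratio)

qc <- do.call(rbind, lapply(specs$sample_id, function(s) {
  q <- depth_distribution_qc(ratios[, s])
  data.frame(sample_id = s, variance = q$variance, skewness = q$skewness,
             flagged = q$flagged)
}))
cl <- cluster_profiles(t(ratios))

message("GC-normalized ", nrow(bins), " bins for ", ncol(counts), " samples")
message("clustering: k = ", cl$k, " (mean silhouette ",
        round(cl$silhouette, 2), ")")
for (k in sort(unique(cl$labels)))
  message("  cluster ", k, ": ",
          paste(names(cl$labels)[cl$labels == k], collapse = ", "))
message(sum(qc$flagged), " sample(s) flagged by depth-distribution QC")

write_bed_bins(cbind(bins, round(ratios, 4)), file.path(out, "ratios.tsv"))
write.table(qc, file.path(out, "qc.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(sample_id = names(cl$labels), cluster = cl$labels),
            file.path(out, "clusters.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
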