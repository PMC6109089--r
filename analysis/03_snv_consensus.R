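#!/usr/bin/env Rscript

# Stage 3: somatic SNV consensus.
#
# Reads the three caller VCFs per tumor sample and the matched-normal calls,
# applies the consensus chain (intra-sample double-calling -> germline
# removal -> cross-sample confident sites -> per-sample Fisher rescue) and
# categorizes the final loci as common / primary-only / ascites-only.

suppressMessages(library(spherophylo))

cfg <- default_config(seed = 1L)
dat <- "results/data"
out <- "results/snv"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

specs <- read.table(file.path(dat, "samples.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
tumor <- specs$sample_id[specs$group != "normal"]
normal_id <- specs$sample_id[specs$group == "normal"][1]
callers <- c("gatk", "varscan", "mutect")

read_sample_calls <- function(s) {
  do.call(rbind, lapply(callers, function(cal) {
    v <- read_vcf(file.path(dat, "vcf", paste0(s, ".", cal, ".vcf")))
    if (nrow(v) == 0) return(NULL)
    cbind(caller_id = cal, sample_id = s, v)
  }))
}
callsets <- do.call(rbind, lapply(tumor, read_sample_calls))
normal_calls <- unique(do.call(rbind, lapply(callers, function(cal)
  read_vcf(file.path(dat, "vcf", paste0(normal_id, ".", cal, ".vcf")))))[
    , c("chrom", "pos", "ref", "alt")])
pileups <- lapply(c(tumor, normal_id), function(s)
  read_pileup_tsv(file.path(dat, "pileup", paste0(s, ".tsv"))))
names(pileups) <- c(tumor, normal_id)

groups <- setNames(specs$group, specs$sample_id)
cons <- build_consensus_table(callsets, pileups, normal_calls, groups,
                              config = cfg$consensus)
cats <- summarize_categories(cons)

message("filter ledger: ",
        paste(names(cons$stage_counts), cons$stage_counts, sep = " = ",
              collapse = ", "))
message("categories of the ", attr(cats, "total"), " final somatic SNVs:")
for (i in seq_len(nrow(cats)))
  message("  ", cats$category[i], ": ", cats$count[i],
          " (", cats$percent[i], "%)")

write.table(cbind(cons$loci, cons$presence * 1L), file.path(out, "consensus.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cons$evidence, file.path(out, "evidence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cats, file.path(out, "categories.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
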