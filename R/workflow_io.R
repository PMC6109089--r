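# File formats (minimal VCF 4.2, BED-like bin tables, pileup TSV, newick),
# pipeline configuration, and the end-to-end driver.

# --- readers / writers --------------------------------------------------

#' Write a call set as a minimal VCF 4.2 file
#'
#' One sample column with AD (ref,alt depths) and DP; positions are written
#' 1-based as the format requires.
#'
#' @param callset data.frame: chrom, pos, ref, alt, alt_depth, total_depth.
#' @param path output file.
#' @param sample_id sample column name.
#' @export
write_vcf <- function(callset, path, sample_id = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_id, sep = "\t"))
  if (nrow(callset) > 0) {
    ref_d <- callset$total_depth - callset$alt_depth
    body <- paste(callset$chrom, callset$pos, ".", callset$ref, callset$alt,
                  ".", "PASS", ".", "GT:AD:DP",
                  paste0("0/1:", ref_d, ",", callset$alt_depth, ":",
                         callset$total_depth),
                  sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a call-set data.frame
#'
#' Multi-allelic records are split into one biallelic row per alternate
#' allele, with its AD entry. Only the first sample column is read.
#'
#' @param path a VCF 4.2 file (plain or gzipped).
#' @return data.frame: chrom, pos (1-based), ref, alt, alt_depth, total_depth.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)     # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      alt_depth = integer(0), total_depth = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty)
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD")[, 1],
                 error = function(e) rep(NA_character_, nrow(fix)))
  dp <- tryCatch(suppressWarnings(
    as.integer(vcfR::extract.gt(v, element = "DP")[, 1])),
    error = function(e) rep(NA_integer_, nrow(fix)))
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ads <- suppressWarnings(as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    rows[[i]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]), ref = fix$REF[i],
      alt = alts,
      alt_depth = if (length(ads) >= 1 + length(alts)) ads[1 + seq_along(alts)]
                  else rep(NA_integer_, length(alts)),
      total_depth = dp[i], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a bin table as BED-like TSV
#'
#' Columns: chrom, start, end (0-based half-open), then any further columns
#' (gc_fraction, counts, ratio, ...).
#' @param bins data.frame of bins.
#' @param path file path.
#' @export
write_bed_bins <- function(bins, path) {
  utils::write.table(bins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bed_bins
#' @export
read_bed_bins <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a per-locus pileup table (chrom, pos, ref, A, C, G, T)
#' @param pileup data.frame pileup.
#' @param path file path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a tree in newick format
#' @param tree an `ape::phylo` (or `mp_tree`).
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "mp_tree")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write simulator ground truth (events per branch) as TSV
#' @param tree a `clone_tree`.
#' @param path file path.
#' @export
write_truth_tsv <- function(tree, path) {
  snv <- data.frame(type = "snv", id = tree$snvs$id, chrom = tree$snvs$chrom,
                    start = tree$snvs$pos, end = tree$snvs$pos,
                    detail = paste0(tree$snvs$ref, ">", tree$snvs$alt),
                    edge = tree$snvs$edge, stringsAsFactors = FALSE)
  cna <- data.frame(type = "cna", id = tree$cnas$id, chrom = tree$cnas$chrom,
                    start = tree$cnas$start, end = tree$cnas$end,
                    detail = ifelse(tree$cnas$direction > 0, "gain", "loss"),
                    edge = tree$cnas$edge, stringsAsFactors = FALSE)
  utils::write.table(rbind(snv, cna), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# --- configuration ------------------------------------------------------

#' Default pipeline configuration (desk-scale study conditions)
#'
#' The default scenario mirrors the study design at desk scale: a clone tree
#' whose ancestral clone splits into a primary-tissue lineage and an ascites
#' lineage; multi-region primary samples, ascites spheroids of good purity,
#' ascites spheroids dominated by normal cells, and a matched normal.
#'
#' @param seed root seed for every random draw.
#' @return Named list of all stage parameters.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = seed,
    # genome / simulator
    genome_scale = 0.01,          # 24 chromosomes, ~36 Mb total
    # ancestral clone C1 splits into a primary-tissue clone C2 and an
    # ascites clone C3, mirroring the early divergence of the two lineages
    n_clones = 3L,
    clone_parents = c("normal", "C1", "C1"),
    n_snvs = 150L,
    n_cnas = 18L,
    n_germline = 30L,
    # samples: 5 primary regions, 3 good-purity spheroids, 2 spheroids
    # dominated by normal cells (the "normal-like" ascites cluster)
    samples = sample_specs(
      sample_id = c("RO1", "RO2", "RO3", "RO4", "LO",
                    "AC1", "AC2", "AC3", "AC4", "AC5", "normal"),
      group = c(rep("primary", 5), rep("ascites", 5), "normal"),
      clone_id = c(rep("C2", 5), rep("C3", 5), "normal"),
      purity = c(0.70, 0.65, 0.70, 0.60, 0.70,
                 0.80, 0.75, 0.80, 0.10, 0.10, 0),
      mean_depth = c(rep(134, 10), 134)),
    wgs_reads_per_bin = 570,      # ~8.5e6 reads over 15,000 bins, scaled
    # binning / CNA
    n_reference_positions = 2e5,
    n_bins = 600L,
    lowess_fraction = 0.3,
    # errors
    error = error_model(ngs_fp_rate = 0.05, wga_fp_rate = 0.05,
                        fn_rate = 0.02, base_error_rate = 0.002),
    # consensus / vaf
    consensus = consensus_config(),
    low_purity_threshold = 0.3,
    vaf_alpha = 0.01,
    background_prob = 1e-4,
    # phylogenetics
    gamma = 50,
    event_delta = 0.7,
    neutral_delta = 0.5
  )
}

#' Smooth synthetic GC track and monotone GC-bias curve
#'
#' `synthetic_gc_fun` gives each genome position a GC fraction varying
#' smoothly along the chromosome (0.33-0.49); `linear_gc_bias` is the
#' default monotone amplification-efficiency curve used by the simulator.
#'
#' @param genome chromosome-length table.
#' @return A function(chrom, pos) -> GC fraction.
#' @export
synthetic_gc_fun <- function(genome) {
  idx <- stats::setNames(seq_len(nrow(genome)), genome$chrom)
  len <- stats::setNames(genome$length, genome$chrom)
  function(chrom, pos) {
    0.41 + 0.08 * sin(2 * pi * (3 * pos / len[chrom] + idx[chrom] / 7))
  }
}

#' @rdname synthetic_gc_fun
#' @param gc GC fraction vector.
#' @export
linear_gc_bias <- function(gc) 0.5 + gc

# --- pipeline driver ----------------------------------------------------

#' Run the full clonal-evolution pipeline on a simulated cohort
#'
#' Stages: simulate (clone tree, binned WGS counts, WES pileups and three
#' caller call sets) -> copy-number profiling (variable bins, Lowess GC
#' normalization, reference scaling, QC, clustering) -> SNV consensus ->
#' VAF/purity/clonality -> event matrices and maximum-parsimony trees.
#' Every intermediate is written under `out_dir` when given. Deterministic
#' given `config$seed`.
#'
#' @param config list from [default_config()] (modify fields as needed).
#' @param out_dir optional output directory for all intermediates.
#' @return list of class `run_report`; see Details.
#' @details The report carries: `stage_counts` (loci surviving each SNV
#'   filter), `categories` (counts and percentages), `clusters`, `qc`,
#'   `purity`, `vaf_tests`, `clonality` (pairwise CI table), `cna_tree`,
#'   `snv_tree`, `rf_cna_vs_snv`, `truth` (the simulated tree and specs),
#'   and `excluded_samples`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  seed <- config$seed
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  save_tsv <- function(x, name) {
    if (!is.null(out_dir))
      utils::write.table(x, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
  }

  # -- simulate ----------------------------------------------------------
  genome <- synthetic_genome(scale = config$genome_scale)
  tree <- simulate_clone_tree(config$n_clones, config$n_snvs, config$n_cnas,
                              genome, seed = seed,
                              parents = config$clone_parents)
  specs <- config$samples
  tumor_ids <- specs$sample_id[specs$group != "normal"]
  normal_id <- specs$sample_id[specs$group == "normal"][1]
  stopifnot(all(specs$clone_id %in% tree$nodes))
  log_stage("simulate", nrow(tree$snvs), " SNVs, ", nrow(tree$cnas),
            " CNAs on ", config$n_clones, " clones; ",
            length(tumor_ids), " tumor samples")
  if (!is.null(out_dir)) {
    write_truth_tsv(tree, file.path(out_dir, "truth_events.tsv"))
    write_newick(true_sample_tree(tree, specs),
                 file.path(out_dir, "truth_tree.nwk"))
  }

  germline <- simulate_germline_loci(config$n_germline, genome, tree, seed)

  # -- CNA profiling -----------------------------------------------------
  set.seed(substream_seed(seed, "reference_positions"))
  npos <- config$n_reference_positions
  ci <- sample.int(nrow(genome), npos, replace = TRUE,
                   prob = genome$length / sum(genome$length))
  ref_pos <- data.frame(chrom = genome$chrom[ci],
                        pos = floor(stats::runif(npos) * genome$length[ci]))
  gc_fun <- synthetic_gc_fun(genome)
  bins <- build_variable_bins(ref_pos, n_bins = config$n_bins,
                              genome = genome, gc_fun = gc_fun)
  counts <- sapply(seq_len(nrow(specs)), function(i) {
    spec <- specs[i, ]
    spec$mean_depth <- config$wgs_reads_per_bin   # spec depth is the WES depth
    simulate_binned_counts(spec, tree, bins,
                           gc_bias = linear_gc_bias, seed = seed)
  })
  colnames(counts) <- specs$sample_id
  norm <- apply(counts, 2, lowess_gc_normalize, gc_per_bin = bins$gc_fraction,
                lowess_fraction = config$lowess_fraction)
  profiles <- lapply(specs$sample_id, function(s)
    estimate_copy_ratio(norm[, s], norm[, normal_id], sample_id = s))
  names(profiles) <- specs$sample_id
  ratio_mat <- t(sapply(profiles, function(p) p$ratio))
  qc <- lapply(profiles, depth_distribution_qc)
  clusters <- cluster_profiles(ratio_mat)
  log_stage("cna", config$n_bins, " bins; ", clusters$k, " clusters")
  save_tsv(cbind(bins, counts), "bins_counts.tsv")
  save_tsv(data.frame(sample = rownames(ratio_mat),
                      cluster = clusters$labels[rownames(ratio_mat)]),
           "clusters.tsv")

  # -- WES simulation + SNV consensus ------------------------------------
  wes <- lapply(seq_len(nrow(specs)), function(i)
    simulate_pileups_and_callsets(specs[i, ], tree, error = config$error,
                                  seed = seed, extra_het_loci = germline))
  names(wes) <- specs$sample_id
  pileups <- lapply(wes, `[[`, "pileup")
  tumor_calls <- do.call(rbind, lapply(wes[tumor_ids], `[[`, "callsets"))
  normal_calls <- unique(
    wes[[normal_id]]$callsets[, c("chrom", "pos", "ref", "alt")])
  groups <- stats::setNames(specs$group, specs$sample_id)
  consensus <- build_consensus_table(tumor_calls, pileups, normal_calls,
                                     groups, config = config$consensus)
  categories <- summarize_categories(consensus)
  log_stage("snv", "stage counts: ",
            paste(names(consensus$stage_counts), consensus$stage_counts,
                  sep = "=", collapse = ", "))
  if (!is.null(out_dir)) {
    for (s in specs$sample_id)
      write_pileup_tsv(pileups[[s]], file.path(out_dir, paste0(s, ".pileup.tsv")))
    save_tsv(cbind(consensus$loci, consensus$presence * 1L), "consensus.tsv")
  }

  # -- VAF / purity / clonality ------------------------------------------
  vafs <- compute_vafs(consensus, pileups)
  purity <- do.call(rbind, lapply(tumor_ids, function(s) {
    est <- estimate_purity(vafs[vafs$sample_id == s, ], sample_id = s,
                           low_purity_threshold = config$low_purity_threshold)
    as.data.frame(est, stringsAsFactors = FALSE)
  }))
  vaf_tests <- do.call(rbind, lapply(tumor_ids, function(s) {
    res <- compare_common_vs_private(vafs[vafs$sample_id == s, ],
                                     group = groups[[s]],
                                     alpha = config$vaf_alpha)
    data.frame(sample_id = s, p_value = res$p_value, verdict = res$verdict,
               stringsAsFactors = FALSE)
  }))
  excluded <- purity$sample_id[purity$low_purity]
  included <- setdiff(tumor_ids, excluded)
  pres <- consensus$presence
  pairs <- utils::combn(included, 2)
  clonality <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    keys <- rownames(pres)
    ci <- clonality_index(keys[pres[, a]], keys[pres[, b]],
                          background_prob = config$background_prob)
    data.frame(sample_a = a, sample_b = b, ci = ci$ci,
               n_shared = ci$n_shared, stringsAsFactors = FALSE)
  }))
  log_stage("vaf", length(excluded), " low-purity sample(s) excluded: ",
            paste(excluded, collapse = ", "))
  save_tsv(purity, "purity.tsv")
  save_tsv(clonality, "clonality.tsv")

  # -- phylogenetics -----------------------------------------------------
  seg_mat <- ratio_mat[included, , drop = FALSE]
  seg_mat <- rbind(seg_mat, normal = ratio_mat[normal_id, ])
  seg_inc <- joint_segmentation(seg_mat, bins, gamma = config$gamma)
  cna_mat <- trinary_matrix(seg_inc, event_delta = config$event_delta,
                            neutral_delta = config$neutral_delta)
  snv_mat <- binary_snv_matrix(consensus, include_samples = included)
  cna_tree <- search_max_parsimony(cna_mat, seed = seed)
  snv_tree <- search_max_parsimony(snv_mat, seed = seed)
  rf <- compare_trees(cna_tree, snv_tree)
  log_stage("phylo", "CNA score ", cna_tree$score, ", SNV score ",
            snv_tree$score, ", RF(CNA,SNV) = ", rf)
  if (!is.null(out_dir)) {
    write_newick(cna_tree, file.path(out_dir, "cna_tree.nwk"))
    write_newick(snv_tree, file.path(out_dir, "snv_tree.nwk"))
  }

  report <- structure(list(
    seed = seed,
    stage_counts = consensus$stage_counts,
    categories = categories,
    total_loci = attr(categories, "total"),
    clusters = clusters, qc = qc,
    purity = purity, vaf_tests = vaf_tests, clonality = clonality,
    consensus = consensus, vafs = vafs,
    segmentation = seg_inc,
    cna_matrix = cna_mat, snv_matrix = snv_mat,
    cna_tree = cna_tree, snv_tree = snv_tree, rf_cna_vs_snv = rf,
    excluded_samples = excluded,
    truth = list(tree = tree, specs = specs, germline = germline)),
    class = "run_report")
  if (!is.null(out_dir))
    save_tsv(report$categories, "categories.tsv")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed ", x$seed, ")\n", sep = "")
  cat("  loci: ", paste(names(x$stage_counts), x$stage_counts, sep = "=",
                        collapse = ", "), "\n", sep = "")
  print(x$categories)
  cat("  clusters: k =", x$clusters$k, "\n")
  cat("  excluded (low purity):", paste(x$excluded_samples, collapse = ", "), "\n")
  cat("  RF(CNA tree, SNV tree) =", x$rf_cna_vs_snv, "\n")
  invisible(x)
}

#' Simulate germline heterozygous loci
#'
#' Draws loci (away from the tree's somatic loci) that are heterozygous in
#' every cell of every sample, including the matched normal — the variants
#' the germline-removal step must catch.
#'
#' @param n number of germline loci.
#' @param genome chromosome-length table.
#' @param tree a `clone_tree` (its somatic loci are avoided).
#' @param seed root seed (substream "germline").
#' @return data.frame: chrom, pos, ref, alt; NULL when `n` is 0.
#' @export
simulate_germline_loci <- function(n, genome, tree, seed) {
  if (n == 0) return(NULL)
  set.seed(substream_seed(seed, "germline"))
  bases <- c("A", "C", "G", "T")
  truth_keys <- paste(tree$snvs$chrom, tree$snvs$pos)
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    m <- n * 2L
    ci <- sample.int(nrow(genome), m, replace = TRUE,
                     prob = genome$length / sum(genome$length))
    pos <- floor(stats::runif(m) * genome$length[ci]) + 1
    ref <- bases[sample.int(4L, m, replace = TRUE)]
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    cand <- data.frame(chrom = genome$chrom[ci], pos = pos, ref = ref,
                       alt = unname(alt), stringsAsFactors = FALSE)
    key <- paste(cand$chrom, cand$pos)
    cand <- cand[!key %in% truth_keys & !duplicated(key), , drop = FALSE]
    out <- unique(rbind(out, cand))
  }
  out[seq_len(n), , drop = FALSE]
}
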