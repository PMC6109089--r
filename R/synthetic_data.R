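#' @keywords internal
"_PACKAGE"

# Seed substreams --------------------------------------------------------

#' Derive a reproducible substream seed from a root seed and a name
#'
#' All randomness in the simulator flows from a single root seed; each
#' sample/stage draws from its own substream so that adding a sample never
#' perturbs the draws of another.
#'
#' @param seed integer root seed.
#' @param name character label of the substream (e.g. a sample id).
#' @return An integer seed < 2^31.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483629
  as.integer((h * 31 + (as.numeric(seed) %% 2147483629)) %% 2147483629)
}

# Genome -----------------------------------------------------------------

#' Construct a synthetic genome (chromosome-length table)
#'
#' Chromosome lengths decrease roughly like the human karyotype; `scale`
#' shrinks the genome for desk-scale simulation while keeping 24 chromosomes.
#'
#' @param n_chrom number of chromosomes.
#' @param scale multiplicative factor on the human-scale lengths.
#' @return data.frame with columns `chrom`, `length`.
#' @export
synthetic_genome <- function(n_chrom = 24, scale = 1) {
  stopifnot(n_chrom >= 1, scale > 0)
  len <- round(seq(2.5e8, 5e7, length.out = n_chrom) * scale)
  data.frame(chrom = paste0("chr", seq_len(n_chrom)),
             length = pmax(len, 10L),
             stringsAsFactors = FALSE)
}

# Clone tree -------------------------------------------------------------

#' Simulate a rooted clone tree with branch-assigned somatic events
#'
#' The root is the normal genotype; the first clone is the ancestral tumor
#' clone, and each further clone descends from a uniformly chosen existing
#' clone. SNV loci are drawn uniformly over the genome; CNA segment lengths
#' are log-uniform between configurable fractions of the host chromosome,
#' arm-scale by default so that each event spans many bins of a binned
#' copy-number profile, as arm-level tumor CNAs do.
#' Every branch receives at least one event, and when the event budget allows
#' (`n_snvs >= n_clones` and `n_cnas >= n_clones`) at least one SNV *and* one
#' CNA, so that trees built from either data type alone can resolve every
#' branch.
#'
#' @param n_clones number of tumor clones (>= 2).
#' @param n_snvs total somatic SNVs to distribute over branches.
#' @param n_cnas total CNA segment events to distribute over branches.
#' @param genome chromosome-length table as from [synthetic_genome()].
#' @param seed integer root seed.
#' @param cna_len_frac length-2 numeric; CNA lengths are log-uniform between
#'   these fractions of the host chromosome length.
#' @param parents optional explicit topology: character vector of length
#'   `n_clones`, parent of clone i ("normal" for the ancestral clone);
#'   otherwise the topology is random.
#' @return An object of class `clone_tree`: nodes, edges (parent -> child),
#'   per-event tables `snvs` and `cnas` with an `edge` column naming the
#'   child clone of the branch carrying the event, and the genome.
#' @export
simulate_clone_tree <- function(n_clones, n_snvs, n_cnas, genome, seed = 1L,
                                cna_len_frac = c(0.3, 0.9), parents = NULL) {
  stopifnot(n_clones >= 2, nrow(genome) >= 1)
  n_edges <- n_clones
  if (n_snvs + n_cnas < n_edges)
    stop("n_snvs + n_cnas must be >= number of branches (", n_edges,
         "): cannot give every branch an event")
  set.seed(substream_seed(seed, "clone_tree"))

  clones <- paste0("C", seq_len(n_clones))
  if (!is.null(parents)) {
    stopifnot(length(parents) == n_clones,
              parents[1] == "normal",
              all(parents[-1] %in% clones))
    parent <- parents
  } else {
    parent <- character(n_clones)
    parent[1] <- "normal"
    if (n_clones > 1) {
      for (i in 2:n_clones) parent[i] <- clones[sample.int(i - 1L, 1L)]
    }
  }
  edges <- data.frame(parent = parent, child = clones, stringsAsFactors = FALSE)

  # assign events to edges: per-type coverage when the budget allows,
  # joint coverage otherwise, surplus uniform
  uniform_edges <- function(n) clones[sample.int(n_edges, n, replace = TRUE)]
  cover_then_uniform <- function(n) c(sample(clones), uniform_edges(n - n_edges))
  snv_edges <- if (n_snvs >= n_edges) cover_then_uniform(n_snvs) else uniform_edges(n_snvs)
  cna_edges <- if (n_cnas >= n_edges) cover_then_uniform(n_cnas) else uniform_edges(n_cnas)
  if (length(setdiff(clones, c(snv_edges, cna_edges))) > 0) {
    perm <- sample(clones)
    k <- min(n_snvs, n_edges)
    snv_edges <- c(perm[seq_len(k)], uniform_edges(n_snvs - k))
    cna_edges <- c(perm[setdiff(seq_len(n_edges), seq_len(k))],
                   uniform_edges(n_cnas - (n_edges - k)))
  }

  total_len <- sum(genome$length)
  draw_loci <- function(n) {
    chrom_idx <- sample.int(nrow(genome), n, replace = TRUE,
                            prob = genome$length / total_len)
    pos <- floor(stats::runif(n) * genome$length[chrom_idx]) + 1
    key <- paste(chrom_idx, pos)
    while (anyDuplicated(key)) {
      d <- which(duplicated(key))
      chrom_idx[d] <- sample.int(nrow(genome), length(d), replace = TRUE,
                                 prob = genome$length / total_len)
      pos[d] <- floor(stats::runif(length(d)) * genome$length[chrom_idx[d]]) + 1
      key <- paste(chrom_idx, pos)
    }
    list(chrom = genome$chrom[chrom_idx], pos = pos)
  }

  bases <- c("A", "C", "G", "T")
  loci <- draw_loci(n_snvs)
  ref <- bases[sample.int(4L, n_snvs, replace = TRUE)]
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  snvs <- data.frame(id = paste0("s", seq_len(n_snvs)),
                     chrom = loci$chrom, pos = loci$pos,
                     ref = ref, alt = unname(alt), edge = snv_edges,
                     stringsAsFactors = FALSE)

  # CNA segments are drawn mutually non-overlapping: clone-defining lesions
  # are distinct regions, so no branch signal is cancelled (gain over loss)
  # or saturated (nested losses) by another branch's event
  cnas <- if (n_cnas > 0) {
    acc <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    shrink <- 1
    for (i in seq_len(n_cnas)) {
      tries <- 0L
      repeat {
        ci <- sample.int(nrow(genome), 1L, prob = genome$length / total_len)
        clen <- genome$length[ci]
        lo <- log(cna_len_frac[1] * clen * shrink)
        hi <- log(cna_len_frac[2] * clen * shrink)
        len <- max(1, round(exp(stats::runif(1) * (hi - lo) + lo)))
        st <- floor(stats::runif(1) * max(1, clen - len))
        en <- min(st + len, clen)
        same <- acc$chrom == genome$chrom[ci]
        if (!any(same & acc$start < en & st < acc$end)) break
        tries <- tries + 1L
        if (tries %% 50L == 0L) shrink <- shrink / 2   # crowded genome
      }
      acc <- rbind(acc, data.frame(chrom = genome$chrom[ci], start = st,
                                   end = en, stringsAsFactors = FALSE))
    }
    data.frame(id = paste0("c", seq_len(n_cnas)),
               chrom = acc$chrom, start = acc$start, end = acc$end,
               direction = sample(c(1L, -1L), n_cnas, replace = TRUE),
               edge = cna_edges, stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(0), chrom = character(0), start = numeric(0),
               end = numeric(0), direction = integer(0), edge = character(0),
               stringsAsFactors = FALSE)
  }

  structure(list(nodes = c("normal", clones), root = "normal", edges = edges,
                 snvs = snvs, cnas = cnas, genome = genome),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("clone_tree:", length(x$nodes) - 1L, "clones,",
      nrow(x$snvs), "SNVs,", nrow(x$cnas), "CNA events\n")
  invisible(x)
}

#' Path from root to a clone (excluding the root)
#' @param tree a `clone_tree`.
#' @param clone a clone id.
#' @return Character vector of clone ids along the root path, root side first.
#' @export
clone_path <- function(tree, clone) {
  if (identical(clone, tree$root)) return(character(0))
  stopifnot(clone %in% tree$nodes)
  path <- clone
  repeat {
    p <- tree$edges$parent[tree$edges$child == path[1]]
    if (p == tree$root) break
    path <- c(p, path)
  }
  path
}

#' Genotype of a clone: events on its root path
#' @inheritParams clone_path
#' @return list with `snvs` and `cnas` data frames (subsets of the tree tables).
#' @export
clone_genotype <- function(tree, clone) {
  path <- clone_path(tree, clone)
  list(snvs = tree$snvs[tree$snvs$edge %in% path, , drop = FALSE],
       cnas = tree$cnas[tree$cnas$edge %in% path, , drop = FALSE])
}

#' Total copy number of a clone in each genomic bin
#'
#' Diploid baseline; each CNA event on the clone's root path shifts the copy
#' number of the bins it covers by +/-1. A bin is covered when its midpoint
#' lies in the segment.
#'
#' @param tree a `clone_tree`.
#' @param clone clone id ("normal" gives all 2s).
#' @param bins data.frame of bins with `chrom`, `start`, `end`.
#' @return Integer vector of per-bin copy numbers (>= 0).
#' @export
clone_copy_number <- function(tree, clone, bins) {
  cn <- rep(2L, nrow(bins))
  if (identical(clone, tree$root)) return(cn)
  cnas <- clone_genotype(tree, clone)$cnas
  if (nrow(cnas) == 0) return(cn)
  mid <- (bins$start + bins$end) / 2
  for (i in seq_len(nrow(cnas))) {
    hit <- bins$chrom == cnas$chrom[i] & mid >= cnas$start[i] & mid < cnas$end[i]
    cn[hit] <- cn[hit] + cnas$direction[i]
  }
  pmax(cn, 0L)
}

# Sample specs and error model -------------------------------------------

#' Build a table of sample specifications
#'
#' @param sample_id character vector of sample ids.
#' @param group one of "primary", "ascites", "normal" per sample.
#' @param clone_id clone carried by each sample ("normal" for the control).
#' @param purity tumor-cell fraction in `[0, 1]`; must be 0 for the normal.
#' @param mean_depth mean sequencing depth (reads per bin for WGS counts,
#'   reads per locus for WES pileups).
#' @return data.frame of class `sample_spec`.
#' @export
sample_specs <- function(sample_id, group, clone_id, purity, mean_depth) {
  stopifnot(all(group %in% c("primary", "ascites", "normal")),
            all(purity >= 0 & purity <= 1),
            all(purity[group == "normal"] == 0))
  out <- data.frame(sample_id = sample_id, group = group, clone_id = clone_id,
                    purity = purity, mean_depth = mean_depth,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_spec", "data.frame")
  out
}

#' Sequencing / amplification error model for the simulator
#'
#' @param ngs_fp_rate expected caller-private false-positive calls per caller,
#'   as a fraction of the number of true somatic loci in the tree.
#' @param wga_fp_rate expected sample-private (amplification-artifact) false
#'   positives per sample, same scale; these are injected into >= 2 callers.
#' @param fn_rate per-caller probability of missing a detectable true locus.
#' @param base_error_rate per-base sequencing error rate used for pileup noise.
#' @param depth_dispersion negative-binomial size for per-locus depth
#'   (Inf = Poisson). Default 55 reproduces the modest overdispersion of
#'   ~134 +/- 21 average exome depth.
#' @return list of class `error_model`.
#' @export
error_model <- function(ngs_fp_rate = 0, wga_fp_rate = 0, fn_rate = 0,
                        base_error_rate = 0, depth_dispersion = 55) {
  rates <- c(ngs_fp_rate, wga_fp_rate, fn_rate, base_error_rate)
  stopifnot(all(rates >= 0), all(rates < 1), depth_dispersion > 0)
  structure(list(ngs_fp_rate = ngs_fp_rate, wga_fp_rate = wga_fp_rate,
                 fn_rate = fn_rate, base_error_rate = base_error_rate,
                 depth_dispersion = depth_dispersion),
            class = "error_model")
}

# Binned read counts (WGS emulation) -------------------------------------

#' Simulate binned whole-genome read counts for one sample
#'
#' The expected count of a bin is
#' `mean_depth * (purity * copy/2 + (1 - purity)) * g(gc)`, with `g`
#' the GC-bias curve rescaled to mean 1, and counts drawn Poisson.
#'
#' @param spec one row of a [sample_specs()] table (data.frame or list).
#' @param tree a `clone_tree`.
#' @param bins bin table with `chrom`, `start`, `end`, `gc_fraction`.
#' @param gc_bias NULL (flat) or a function of GC fraction returning relative
#'   efficiency.
#' @param seed root seed; the draw uses the substream named by the sample id.
#' @return Integer vector of per-bin counts.
#' @export
simulate_binned_counts <- function(spec, tree, bins, gc_bias = NULL, seed = 1L) {
  if (is.data.frame(spec)) spec <- as.list(spec[1, ])
  if (nrow(bins) == 0) stop("empty bins")
  set.seed(substream_seed(seed, paste0("wgs:", spec$sample_id)))
  cn <- if (spec$purity > 0) clone_copy_number(tree, spec$clone_id, bins)
        else rep(2L, nrow(bins))
  mix <- spec$purity * cn / 2 + (1 - spec$purity)
  g <- if (is.null(gc_bias)) rep(1, nrow(bins)) else gc_bias(bins$gc_fraction)
  g <- g / mean(g)
  stats::rpois(nrow(bins), spec$mean_depth * mix * g)
}

# Pileups and caller call sets (WES emulation) ---------------------------

#' Simulate per-locus pileups and three caller call sets for one sample
#'
#' True somatic loci of the sample's clone receive alt reads
#' Binomial(depth, purity/2) (diploid heterozygous). Each of three callers
#' reports true loci with enough alt support, minus false-negative draws,
#' plus caller-private NGS false positives; amplification (WGA) false
#' positives are sample-private and injected into at least two callers with
#' real-looking allele support. Pileups are reported at every somatic locus
#' of the whole tree (so every sample can be interrogated at every candidate
#' locus) plus this sample's false-positive loci.
#'
#' @inheritParams simulate_binned_counts
#' @param error an [error_model()].
#' @param min_alt minimum alt reads for a caller to call a locus (default 2).
#' @param extra_het_loci optional data.frame (chrom, pos, ref, alt) of
#'   germline heterozygous loci present in every cell (VAF 0.5 regardless of
#'   purity), e.g. shared with the matched normal.
#' @return list with `pileup` (chrom, pos, ref, A, C, G, T) and `callsets`,
#'   a data.frame with columns caller_id, sample_id, chrom, pos, ref, alt,
#'   alt_depth, total_depth and an `origin` flag in
#'   {"somatic", "germline", "ngs_fp", "wga_fp"} for ground-truth bookkeeping.
#' @export
simulate_pileups_and_callsets <- function(spec, tree, error = error_model(),
                                          seed = 1L, min_alt = 2L,
                                          extra_het_loci = NULL) {
  if (is.data.frame(spec)) spec <- as.list(spec[1, ])
  set.seed(substream_seed(seed, paste0("wes:", spec$sample_id)))

  truth <- clone_genotype(tree, spec$clone_id)$snvs
  all_loci <- tree$snvs
  n_cand <- max(1L, nrow(all_loci))
  extra <- if (is.null(extra_het_loci)) all_loci[0, c("chrom", "pos", "ref", "alt")]
           else extra_het_loci[, c("chrom", "pos", "ref", "alt")]

  rdepth <- function(n) {
    if (is.infinite(error$depth_dispersion)) stats::rpois(n, spec$mean_depth)
    else stats::rnbinom(n, mu = spec$mean_depth, size = error$depth_dispersion)
  }

  # false-positive loci, drawn away from every clone's true loci
  draw_fp <- function(n, existing_keys) {
    if (n == 0L) return(all_loci[0, c("chrom", "pos", "ref", "alt")])
    g <- tree$genome
    out <- NULL
    bases <- c("A", "C", "G", "T")
    while (is.null(out) || nrow(out) < n) {
      m <- n * 2L
      ci <- sample.int(nrow(g), m, replace = TRUE, prob = g$length / sum(g$length))
      pos <- floor(stats::runif(m) * g$length[ci]) + 1
      ref <- bases[sample.int(4L, m, replace = TRUE)]
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
      cand <- data.frame(chrom = g$chrom[ci], pos = pos, ref = ref,
                         alt = unname(alt), stringsAsFactors = FALSE)
      key <- paste(cand$chrom, cand$pos)
      cand <- cand[!key %in% existing_keys & !duplicated(key), , drop = FALSE]
      out <- unique(rbind(out, cand))
    }
    out[seq_len(n), , drop = FALSE]
  }

  truth_keys <- c(paste(all_loci$chrom, all_loci$pos),
                  paste(extra$chrom, extra$pos))
  n_ngs <- stats::rpois(3L, error$ngs_fp_rate * n_cand)   # one draw per caller
  n_wga <- stats::rpois(1L, error$wga_fp_rate * n_cand)
  ngs_fp <- draw_fp(sum(n_ngs), truth_keys)
  wga_fp <- draw_fp(n_wga, c(truth_keys, paste(ngs_fp$chrom, ngs_fp$pos)))

  # pileup over all candidate loci + germline + this sample's FP loci
  pl <- rbind(all_loci[, c("chrom", "pos", "ref", "alt")],
              extra, ngs_fp, wga_fp)
  n <- nrow(pl)
  depth <- rdepth(n)
  is_true <- paste(pl$chrom, pl$pos) %in% paste(truth$chrom, truth$pos)
  is_germ <- seq_len(n) > nrow(all_loci) &
             seq_len(n) <= nrow(all_loci) + nrow(extra)
  is_wga <- seq_len(n) > (nrow(all_loci) + nrow(extra) + nrow(ngs_fp))
  vaf <- numeric(n)
  vaf[is_true] <- spec$purity / 2
  vaf[is_germ] <- 0.5
  vaf[is_wga] <- stats::runif(sum(is_wga), 0.15, 0.5)  # artifact looks allelic
  alt_count <- stats::rbinom(n, depth, vaf)
  alt_count[is_wga] <- pmax(alt_count[is_wga], pmin(depth[is_wga], 1L))

  counts <- matrix(0L, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  bases <- c("A", "C", "G", "T")
  # base-error noise on the two non-ref, non-alt bases
  for (b in bases) {
    other <- pl$ref != b & pl$alt != b
    if (error$base_error_rate > 0 && any(other))
      counts[other, b] <- stats::rbinom(sum(other), depth[other],
                                        error$base_error_rate / 3)
  }
  for (i in seq_len(n)) counts[i, pl$alt[i]] <- alt_count[i]
  ref_count <- pmax(depth - rowSums(counts), 0L)
  for (i in seq_len(n)) counts[i, pl$ref[i]] <- counts[i, pl$ref[i]] + ref_count[i]

  pileup <- data.frame(chrom = pl$chrom, pos = pl$pos, ref = pl$ref,
                       counts, stringsAsFactors = FALSE)

  callers <- c("gatk", "varscan", "mutect")
  mk_calls <- function(idx, caller, origin) {
    if (length(idx) == 0L)
      return(data.frame(caller_id = character(0), sample_id = character(0),
                        chrom = character(0), pos = numeric(0),
                        ref = character(0), alt = character(0),
                        alt_depth = integer(0), total_depth = integer(0),
                        origin = character(0), stringsAsFactors = FALSE))
    data.frame(caller_id = caller, sample_id = spec$sample_id,
               chrom = pl$chrom[idx], pos = pl$pos[idx],
               ref = pl$ref[idx], alt = pl$alt[idx],
               alt_depth = alt_count[idx],
               total_depth = depth[idx],
               origin = origin, stringsAsFactors = FALSE)
  }

  true_idx <- which(is_true)
  germ_idx <- which(is_germ)
  detectable <- true_idx[alt_count[true_idx] >= min_alt]
  germ_detectable <- germ_idx[alt_count[germ_idx] >= min_alt]
  calls <- list()
  for (k in seq_along(callers)) {
    keep <- detectable[stats::runif(length(detectable)) >= error$fn_rate]
    calls[[length(calls) + 1L]] <- mk_calls(keep, callers[k], "somatic")
    keepg <- germ_detectable[stats::runif(length(germ_detectable)) >= error$fn_rate]
    calls[[length(calls) + 1L]] <- mk_calls(keepg, callers[k], "germline")
  }
  # caller-private NGS FPs
  if (nrow(ngs_fp) > 0) {
    fp_idx <- nrow(all_loci) + nrow(extra) + seq_len(nrow(ngs_fp))
    owner <- rep(seq_along(callers), times = n_ngs)
    for (k in seq_along(callers))
      calls[[length(calls) + 1L]] <- mk_calls(fp_idx[owner == k], callers[k], "ngs_fp")
  }
  # sample-private WGA FPs: seen by >= 2 callers of this sample
  if (nrow(wga_fp) > 0) {
    wga_idx <- nrow(all_loci) + nrow(extra) + nrow(ngs_fp) + seq_len(nrow(wga_fp))
    for (i in seq_along(wga_idx)) {
      nk <- sample(2:3, 1L)
      for (k in sample.int(3L, nk))
        calls[[length(calls) + 1L]] <- mk_calls(wga_idx[i], callers[k], "wga_fp")
    }
  }
  callsets <- do.call(rbind, calls)
  callsets <- callsets[order(callsets$caller_id, callsets$chrom, callsets$pos), ]
  rownames(callsets) <- NULL
  list(pileup = pileup, callsets = callsets)
}

# True sample tree -------------------------------------------------------

#' Ground-truth phylogeny over samples implied by a clone tree
#'
#' Each sampled clone contributes a pendant leaf attached at its node in the
#' clone tree; a "normal" leaf is attached at the root. Nodes of degree two
#' are suppressed, so ancestral clones that were sampled appear as leaves on
#' (possibly multifurcating) internal nodes.
#'
#' @param tree a `clone_tree`.
#' @param specs a [sample_specs()] table; samples with group "normal" map to
#'   the root. Several samples may share a clone.
#' @return An `ape::phylo` object (unrooted comparisons are up to the caller).
#' @export
true_sample_tree <- function(tree, specs) {
  tumor <- specs[specs$group != "normal", , drop = FALSE]
  # newick via recursive descent over the clone tree
  children_of <- function(node) tree$edges$child[tree$edges$parent == node]
  leaves_at <- function(node) {
    ids <- tumor$sample_id[tumor$clone_id == node]
    if (identical(node, tree$root)) ids <- c(ids, "normal")
    ids
  }
  descend <- function(node) {
    parts <- c(leaves_at(node), vapply(children_of(node), descend, character(1)))
    if (length(parts) == 1L) parts else paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- descend(tree$root)
  if (!startsWith(txt, "(")) txt <- paste0("(", txt, ")")
  phy <- ape::read.tree(text = paste0(txt, ";"))
  ape::collapse.singles(phy)
}
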