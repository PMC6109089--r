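# VAF distributions, tumor purity from clonal VAFs, common-vs-private
# comparison, and the clonality index for sample pairs.

#' Variant allele frequencies for the loci of a consensus table
#'
#' For every (locus, sample) pair with present status, VAF = alt reads /
#' total reads at the locus from that sample's pileup. Records at zero-depth
#' pileups are dropped with a warning.
#'
#' @param consensus a `consensus_table`.
#' @param pileups named list (by sample id) of pileup tables.
#' @param present_only keep only present loci (default TRUE); otherwise all
#'   confident loci are queried in all samples (absent loci give their
#'   background VAF, typically ~0).
#' @return data.frame: sample_id, chrom, pos, ref, alt, category, vaf,
#'   alt_depth, total_depth.
#' @export
compute_vafs <- function(consensus, pileups, present_only = TRUE) {
  loci <- consensus$loci
  samples <- colnames(consensus$presence)
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (s in samples) {
    pl <- pileups[[s]]
    pl_key <- paste(pl$chrom, pl$pos)
    idx <- if (present_only) which(consensus$presence[, s]) else seq_len(nrow(loci))
    if (length(idx) == 0) next
    j <- match(paste(loci$chrom[idx], loci$pos[idx]), pl_key)
    keep <- !is.na(j)
    idx <- idx[keep]; j <- j[keep]
    cnt <- as.matrix(pl[j, bases])
    depth <- rowSums(cnt)
    alt_d <- cnt[cbind(seq_along(idx), match(loci$alt[idx], bases))]
    if (any(depth == 0)) {
      warning(sum(depth == 0), " zero-depth record(s) dropped in sample ", s)
      nz <- depth > 0
      idx <- idx[nz]; alt_d <- alt_d[nz]; depth <- depth[nz]
    }
    if (length(idx) == 0) next
    out[[s]] <- data.frame(sample_id = s, loci[idx, c("chrom", "pos", "ref", "alt")],
                           category = loci$category[idx],
                           vaf = alt_d / depth, alt_depth = alt_d,
                           total_depth = depth, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare VAFs of common versus group-private mutations in one sample
#'
#' In a sample harboring subclones, mutations shared across the whole tumor
#' (common) sit at higher allele frequency than mutations private to the
#' sample's group; a one-sided Mann-Whitney U test (common > private)
#' detects this subclonal structure.
#'
#' @param vafs `compute_vafs()` records of one sample.
#' @param group the sample's group ("primary" or "ascites"); selects which
#'   private category to compare against.
#' @param alpha significance level (default 0.01).
#' @param min_n minimum records per category to test (default 3).
#' @return list: p_value, verdict ("subclonal structure", "no difference",
#'   or "not testable"), n_common, n_private.
#' @export
compare_common_vs_private <- function(vafs, group, alpha = 0.01, min_n = 3L) {
  private_cat <- if (group == "primary") "primary_only" else "ascites_only"
  x <- vafs$vaf[vafs$category == "common"]
  y <- vafs$vaf[vafs$category == private_cat]
  if (length(x) < min_n || length(y) < min_n)
    return(list(p_value = NA_real_, verdict = "not testable",
                n_common = length(x), n_private = length(y)))
  p <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
  list(p_value = p,
       verdict = if (p < alpha) "subclonal structure" else "no difference",
       n_common = length(x), n_private = length(y))
}

#' Estimate tumor purity from clonal (common) VAFs
#'
#' Clonal heterozygous SNVs in a diploid region of a sample of purity `p`
#' sit at VAF `p/2`, so purity is estimated as `min(1, 2 x median VAF)` over
#' common-category loci. Samples below the purity threshold are flagged and
#' excluded from phylogenetic reconstruction (their event profiles look
#' normal-like regardless of the clone they carry).
#'
#' @param vafs `compute_vafs()` records of one sample.
#' @param sample_id label carried into the result.
#' @param low_purity_threshold flag threshold (default 0.3).
#' @param min_n minimum common-category records (default 3).
#' @return list: sample_id, purity, low_purity, n_loci.
#' @export
estimate_purity <- function(vafs, sample_id = NA_character_,
                            low_purity_threshold = 0.3, min_n = 3L) {
  v <- vafs$vaf[vafs$category == "common"]
  if (length(v) < min_n)
    return(list(sample_id = sample_id, purity = NA_real_, low_purity = TRUE,
                n_loci = length(v)))
  purity <- min(1, 2 * stats::median(v))
  list(sample_id = sample_id, purity = purity,
       low_purity = purity < low_purity_threshold, n_loci = length(v))
}

#' Clonality index for a pair of mutation profiles
#'
#' Likelihood-ratio index of clonal relatedness versus independent origin.
#' Under independence, both samples acquiring the same rare mutation (per-
#' locus background probability `p_i`) is vanishingly unlikely, so each
#' shared locus contributes a factor `1/p_i` in favor of clonality; each
#' discordant (private) locus contributes a penalty factor
#' `discordance_penalty` < 1, reflecting that a truly clonal pair should
#' share most of its mutations. The index is `CI = LR / (1 + LR)`, in
#' `[0, 1]`; with no shared mutation the index is defined as 0.
#'
#' @param loci_a,loci_b character vectors of locus keys (or data.frames with
#'   chrom/pos/alt columns) for the two samples.
#' @param background_prob per-locus background mutation probability: scalar
#'   applied to all loci or a named vector over the shared loci.
#' @param discordance_penalty per-discordant-locus likelihood factor
#'   (default 0.1).
#' @return list of class `clonality_result`: ci, log_lr, n_shared,
#'   n_private_a, n_private_b, background_prob.
#' @export
clonality_index <- function(loci_a, loci_b, background_prob = 1e-4,
                            discordance_penalty = 0.1) {
  as_keys <- function(x) {
    if (is.data.frame(x)) paste(x$chrom, x$pos, x$alt, sep = ":") else as.character(x)
  }
  a <- unique(as_keys(loci_a)); b <- unique(as_keys(loci_b))
  if (length(a) < 1 || length(b) < 1)
    stop("both samples need at least one somatic locus")
  if (any(background_prob <= 0) || any(background_prob >= 1))
    stop("background probabilities must lie strictly between 0 and 1")
  if (discordance_penalty <= 0 || discordance_penalty >= 1)
    stop("discordance_penalty must lie strictly between 0 and 1")
  shared <- intersect(a, b)
  n_shared <- length(shared)
  n_pa <- length(setdiff(a, b)); n_pb <- length(setdiff(b, a))
  if (n_shared == 0)
    return(structure(list(ci = 0, log_lr = -Inf, n_shared = 0L,
                          n_private_a = n_pa, n_private_b = n_pb,
                          background_prob = background_prob),
                     class = "clonality_result"))
  p <- if (length(background_prob) == 1) rep(background_prob, n_shared)
       else background_prob[shared]
  log_lr <- sum(-log(p)) + (n_pa + n_pb) * log(discordance_penalty)
  structure(list(ci = stats::plogis(log_lr), log_lr = log_lr,
                 n_shared = n_shared, n_private_a = n_pa, n_private_b = n_pb,
                 background_prob = background_prob),
            class = "clonality_result")
}

#' @export
print.clonality_result <- function(x, ...) {
  cat(sprintf("clonality index CI = %.1f (shared %d, private %d/%d)\n",
              x$ci, x$n_shared, x$n_private_a, x$n_private_b))
  invisible(x)
}
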