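# Three-caller somatic SNV consensus: intra-sample double-calling,
# germline removal, cross-sample confident sites, and Fisher-exact rescue.

locus_key <- function(df) paste(df$chrom, df$pos, df$alt, sep = ":")

#' Consensus-filter configuration
#'
#' @param min_callers callers that must agree within a sample (default 2).
#' @param min_samples samples in which a variant must be double-called to be
#'   a confident site (default 2).
#' @param fisher_alpha rescue significance level (default 1e-3).
#' @return list of class `consensus_config`.
#' @export
consensus_config <- function(min_callers = 2L, min_samples = 2L,
                             fisher_alpha = 1e-3) {
  stopifnot(min_callers %in% c(2L, 3L), fisher_alpha > 0, fisher_alpha < 1,
            min_samples >= 1)
  structure(list(min_callers = as.integer(min_callers),
                 min_samples = as.integer(min_samples),
                 fisher_alpha = fisher_alpha),
            class = "consensus_config")
}

#' Intra-sample double-called sites
#'
#' Variants reported by at least `min_callers` of the three callers of one
#' sample. Agreement is on (chrom, pos, alt): the same position with a
#' different alternate allele is a different variant.
#'
#' @param callsets data.frame of one sample's calls from all three callers
#'   (columns caller_id, chrom, pos, ref, alt, ...).
#' @param config a [consensus_config()].
#' @return data.frame of loci: chrom, pos, ref, alt, n_callers.
#' @export
intra_sample_double_called <- function(callsets, config = consensus_config()) {
  callers <- unique(callsets$caller_id)
  if (length(callers) != 3L)
    stop("expected call sets from exactly 3 distinct callers, got ",
         length(callers))
  per_caller <- split(callsets, callsets$caller_id)
  if (any(vapply(per_caller, function(d) anyDuplicated(locus_key(d)) > 0, logical(1))))
    stop("duplicate locus within one caller's call set")
  key <- locus_key(callsets)
  tab <- table(key)
  keep <- names(tab)[tab >= config$min_callers]
  first <- callsets[!duplicated(key) & key %in% keep,
                    c("chrom", "pos", "ref", "alt"), drop = FALSE]
  first$n_callers <- as.integer(tab[locus_key(first)])
  first <- first[order(first$chrom, first$pos, first$alt), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Remove germline variants seen in the matched normal
#'
#' @param loci data.frame with chrom, pos, alt (and any other columns).
#' @param normal_callset data.frame of variants called in the matched normal.
#' @return `loci` minus rows whose (chrom, pos, alt) appears in the normal.
#' @export
remove_germline <- function(loci, normal_callset) {
  if (is.null(normal_callset) || nrow(normal_callset) == 0) return(loci)
  out <- loci[!(locus_key(loci) %in% locus_key(normal_callset)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confident sites: double-called in at least `min_samples` samples
#'
#' Whole-genome-amplification artifacts are private to one sample (each
#' amplification reaction makes its own errors), so requiring recurrence
#' across samples removes them.
#'
#' @param double_called_by_sample named list of per-sample double-called loci
#'   (as from [intra_sample_double_called()], after germline removal).
#' @param config a [consensus_config()].
#' @return data.frame of confident loci: chrom, pos, ref, alt, n_samples.
#' @export
confident_sites <- function(double_called_by_sample,
                            config = consensus_config()) {
  if (length(double_called_by_sample) < 2)
    stop("need double-called sets from at least 2 samples")
  keys <- lapply(double_called_by_sample, locus_key)
  tab <- table(unlist(keys, use.names = FALSE))
  keep <- names(tab)[tab >= config$min_samples]
  all_loci <- do.call(rbind, lapply(double_called_by_sample, function(d)
    d[, c("chrom", "pos", "ref", "alt"), drop = FALSE]))
  k <- locus_key(all_loci)
  out <- all_loci[!duplicated(k) & k %in% keep, , drop = FALSE]
  out$n_samples <- as.integer(tab[locus_key(out)])
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher-exact rescue of a variant at a confident site
#'
#' A variant at a confident site is accepted in a sample when at least one
#' caller reported it there *and* its allele count is significantly larger
#' than that of the other non-reference bases: one-sided Fisher's exact test
#' on the 2x2 table `[[alt, depth - alt], [other_max, depth - other_max]]`
#' where `other_max` is the larger count of the two non-reference, non-alt
#' bases (the conservative comparator).
#'
#' @param pileup_row one row of a pileup table (chrom, pos, ref, A, C, G, T).
#' @param alt alternate allele (single base, different from ref).
#' @param any_caller_called did any of the sample's callers report it?
#' @param config a [consensus_config()].
#' @return list: present (logical), p_value, alt_count, other_max, depth.
#' @export
fisher_rescue <- function(pileup_row, alt, any_caller_called,
                          config = consensus_config()) {
  ref <- pileup_row$ref
  if (identical(alt, ref)) stop("alt allele equals the reference base")
  bases <- c("A", "C", "G", "T")
  cnt <- as.numeric(pileup_row[bases])
  depth <- sum(cnt)
  if (depth <= 0) stop("pileup depth is zero")
  alt_count <- cnt[match(alt, bases)]
  other <- setdiff(bases, c(ref, alt))
  other_max <- max(cnt[match(other, bases)])
  tab <- matrix(c(alt_count, depth - alt_count,
                  other_max, depth - other_max),
                nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(present = isTRUE(any_caller_called) && p < config$fisher_alpha,
       p_value = p, alt_count = alt_count, other_max = other_max,
       depth = depth)
}

#' Build the consensus somatic SNV table across samples
#'
#' Applies the full chain: per-sample intra-sample double-calling, germline
#' removal against the matched normal, cross-sample confident sites, then
#' per-sample Fisher rescue at every confident site (samples where the site
#' was double-called are trivially present). Finally, each locus is
#' categorized by the groups of the samples carrying it: `common` (at least
#' one primary and one ascites sample), `primary_only`, or `ascites_only`.
#'
#' @param callsets data.frame of all tumor-sample calls (caller_id,
#'   sample_id, chrom, pos, ref, alt, ...); three callers per sample.
#' @param pileups named list (by sample id) of pileup tables.
#' @param normal_callset matched-normal variant calls (germline filter).
#' @param groups named character vector: sample id -> "primary"/"ascites".
#' @param config a [consensus_config()].
#' @return list of class `consensus_table`:
#'   `loci` (chrom, pos, ref, alt, category),
#'   `presence` (loci x samples logical matrix),
#'   `evidence` (long data.frame: locus key, sample, n_callers, fisher_p),
#'   `stage_counts` (loci surviving each filter stage).
#' @export
build_consensus_table <- function(callsets, pileups, normal_callset, groups,
                                  config = consensus_config()) {
  samples <- unique(callsets$sample_id)
  if (length(samples) < 2) stop("need at least 2 tumor samples")
  if (!all(samples %in% names(groups)))
    stop("every sample needs a group label")
  per_sample <- split(callsets, callsets$sample_id)

  dc <- lapply(per_sample, intra_sample_double_called, config = config)
  n_dc <- length(unique(unlist(lapply(dc, locus_key))))
  dc <- lapply(dc, remove_germline, normal_callset = normal_callset)
  n_germ <- length(unique(unlist(lapply(dc, locus_key))))
  conf <- confident_sites(dc, config = config)

  presence <- matrix(FALSE, nrow(conf), length(samples),
                     dimnames = list(locus_key(conf), samples))
  ev <- vector("list", length(samples))
  for (s in samples) {
    calls_s <- per_sample[[s]]
    dc_keys <- locus_key(dc[[s]])
    pl <- pileups[[s]]
    pl_key <- paste(pl$chrom, pl$pos)
    conf_keys <- locus_key(conf)
    caller_keys <- lapply(split(calls_s, calls_s$caller_id), locus_key)
    n_call <- Reduce(`+`, lapply(caller_keys, function(kk)
      as.integer(conf_keys %in% kk)))
    fp <- numeric(nrow(conf))
    pres <- logical(nrow(conf))
    for (i in seq_len(nrow(conf))) {
      k <- conf_keys[i]
      j <- match(paste(conf$chrom[i], conf$pos[i]), pl_key)
      if (is.na(j)) {
        warning("no pileup for confident site ", k, " in sample ", s,
                "; status set absent")
        fp[i] <- NA_real_
        pres[i] <- FALSE
        next
      }
      rs <- fisher_rescue(pl[j, ], conf$alt[i],
                          any_caller_called = n_call[i] >= 1, config = config)
      fp[i] <- rs$p_value
      pres[i] <- (k %in% dc_keys) || rs$present
    }
    presence[, s] <- pres
    ev[[match(s, samples)]] <- data.frame(locus = locus_key(conf), sample = s,
                                          n_callers = n_call, fisher_p = fp,
                                          stringsAsFactors = FALSE)
  }

  grp <- groups[samples]
  in_primary <- rowSums(presence[, grp == "primary", drop = FALSE]) > 0
  in_ascites <- rowSums(presence[, grp == "ascites", drop = FALSE]) > 0
  category <- ifelse(in_primary & in_ascites, "common",
                     ifelse(in_primary, "primary_only",
                            ifelse(in_ascites, "ascites_only", "none")))
  loci <- conf[, c("chrom", "pos", "ref", "alt")]
  loci$category <- category

  structure(list(loci = loci, presence = presence,
                 evidence = do.call(rbind, ev),
                 stage_counts = c(double_called = n_dc,
                                  after_germline = n_germ,
                                  confident = nrow(conf),
                                  final = sum(category != "none"))),
            class = "consensus_table")
}

#' @export
print.consensus_table <- function(x, ...) {
  cat("consensus_table:", nrow(x$loci), "loci x", ncol(x$presence), "samples\n")
  print(table(x$loci$category))
  invisible(x)
}

#' Category counts and percentages of a consensus table
#'
#' @param x a `consensus_table`, or a named vector of counts with names
#'   common / primary_only / ascites_only.
#' @return data.frame with category, count, percent (one decimal), plus a
#'   `total` attribute.
#' @export
summarize_categories <- function(x) {
  counts <- if (inherits(x, "consensus_table")) {
    tab <- table(factor(x$loci$category,
                        levels = c("common", "primary_only", "ascites_only")))
    stats::setNames(as.integer(tab), names(tab))
  } else {
    x[c("common", "primary_only", "ascites_only")]
  }
  total <- sum(counts)
  pct <- if (total > 0) round(counts / total * 100, 1) else counts * NA_real_
  out <- data.frame(category = names(counts), count = as.integer(counts),
                    percent = as.numeric(pct), stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}
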