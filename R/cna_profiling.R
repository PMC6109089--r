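# Copy-number profiling: variable-size binning, GC normalization,
# reference scaling, QC, and clustering of profiles.

#' Divide the genome into variable-sized bins with equal expected reads
#'
#' Bin boundaries are placed so that each bin contains the same number of
#' uniquely-mappable reference positions (within one, by construction), so
#' that a uniformly sequenced diploid sample has an equal expected read count
#' in every bin regardless of local mappability. The per-chromosome bin quota
#' is apportioned by the chromosome's share of reference positions
#' (largest-remainder rounding); bins never span a chromosome boundary.
#' Coordinates are 0-based, half-open (BED convention).
#'
#' @param reference_positions data.frame with `chrom` and `pos` of uniquely
#'   mapped reference read starts (need not be sorted).
#' @param n_bins total number of bins over the genome (default 15000).
#' @param genome optional chromosome-length table; when given, the first bin
#'   of a chromosome starts at 0 and the last ends at the chromosome length,
#'   otherwise at the observed position range.
#' @param gc_fun optional function(chrom, midpoint) -> GC fraction used to
#'   annotate bins; otherwise `gc_fraction` is NA.
#' @return data.frame of bins: chrom, start, end, gc_fraction, expected_reads
#'   (the number of reference positions in the bin).
#' @export
build_variable_bins <- function(reference_positions, n_bins = 15000,
                                genome = NULL, gc_fun = NULL) {
  stopifnot(n_bins >= 1)
  N <- nrow(reference_positions)
  if (N < n_bins)
    stop("fewer reference positions (", N, ") than requested bins (", n_bins, ")")
  counts <- table(reference_positions$chrom)
  chroms <- names(counts)
  # largest-remainder apportionment of the bin quota
  raw <- as.numeric(counts) / N * n_bins
  quota <- floor(raw)
  quota[quota == 0 & as.numeric(counts) > 0] <- 1   # every covered chrom gets a bin
  short <- n_bins - sum(quota)
  if (short > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    take <- rep(0L, length(quota))
    i <- 1L
    while (short > 0) {
      take[ord[(i - 1L) %% length(ord) + 1L]] <- take[ord[(i - 1L) %% length(ord) + 1L]] + 1L
      short <- short - 1L; i <- i + 1L
    }
    quota <- quota + take
  } else if (short < 0) {
    ord <- order(quota, decreasing = TRUE)
    i <- 1L
    while (short < 0) {
      j <- ord[(i - 1L) %% length(ord) + 1L]
      if (quota[j] > 1L) { quota[j] <- quota[j] - 1L; short <- short + 1L }
      i <- i + 1L
    }
  }
  names(quota) <- chroms
  if (any(quota > as.numeric(counts)))
    stop("a chromosome was apportioned more bins than it has positions; ",
         "reduce n_bins or supply more reference positions")

  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    pos <- sort(reference_positions$pos[reference_positions$chrom == ch])
    k <- quota[[ci]]
    n <- length(pos)
    # split sorted positions into k groups of floor/ceil size
    grp_sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) grp_sizes[seq_len(extra)] <- grp_sizes[seq_len(extra)] + 1L
    ends_idx <- cumsum(grp_sizes)
    starts_idx <- c(1L, utils::head(ends_idx, -1L) + 1L)
    span_lo <- if (!is.null(genome)) 0 else pos[1]
    span_hi <- if (!is.null(genome)) genome$length[genome$chrom == ch] else pos[n] + 1
    # boundary = first position of the next group; half-open bins
    starts <- c(span_lo, pos[starts_idx[-1L]])
    ends <- c(starts[-1L], span_hi)
    out[[ci]] <- data.frame(chrom = ch, start = starts, end = ends,
                            expected_reads = grp_sizes, stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, out)
  rownames(bins) <- NULL
  mid <- (bins$start + bins$end) / 2
  bins$gc_fraction <- if (is.null(gc_fun)) NA_real_ else gc_fun(bins$chrom, mid)
  bins[, c("chrom", "start", "end", "gc_fraction", "expected_reads")]
}

#' Count reads in bins
#'
#' A read is assigned to the bin whose half-open interval `[start, end)`
#' contains its start position; reads outside the covered territory are
#' dropped.
#'
#' @param read_positions data.frame with `chrom`, `pos` (read starts).
#' @param bins bin table from [build_variable_bins()].
#' @return Integer vector of counts, one per bin.
#' @export
count_reads_in_bins <- function(read_positions, bins) {
  counts <- integer(nrow(bins))
  for (ch in unique(bins$chrom)) {
    bi <- which(bins$chrom == ch)
    pos <- read_positions$pos[read_positions$chrom == ch]
    if (length(pos) == 0) next
    brk <- c(bins$start[bi], bins$end[bi[length(bi)]])
    idx <- findInterval(pos, brk, left.open = FALSE, rightmost.closed = FALSE)
    ok <- idx >= 1 & idx <= length(bi) & pos < bins$end[bi[length(bi)]]
    tab <- tabulate(idx[ok], nbins = length(bi))
    counts[bi] <- counts[bi] + tab
  }
  counts
}

#' Lowess GC normalization of binned read counts
#'
#' Fits a Lowess trend of count versus GC fraction, divides counts by the
#' fitted trend, and rescales so the genome-wide median is unchanged. This
#' removes the monotone amplification/sequencing efficiency trend with GC
#' without disturbing copy-number signal, which is local in genome position
#' but not in GC.
#'
#' @param counts numeric vector of per-bin counts (or depths).
#' @param gc_per_bin GC fraction per bin.
#' @param lowess_fraction Lowess smoother span (default 0.3).
#' @param iter robustifying iterations (default 1).
#' @return Numeric vector of normalized depths, same length as `counts`.
#' @export
lowess_gc_normalize <- function(counts, gc_per_bin, lowess_fraction = 0.3,
                                iter = 1L) {
  stopifnot(length(counts) == length(gc_per_bin), lowess_fraction > 0,
            lowess_fraction <= 1)
  if (length(counts) < 10) stop("need at least 10 bins to fit a GC trend")
  if (length(unique(gc_per_bin)) == 1L) {
    warning("all bins share one GC value; no trend fittable, counts unchanged")
    return(as.numeric(counts))
  }
  fit <- stats::lowess(gc_per_bin, counts, f = lowess_fraction, iter = iter)
  trend <- stats::approx(fit$x, fit$y, xout = gc_per_bin, rule = 2, ties = mean)$y
  trend[trend <= 0] <- min(trend[trend > 0], 1e-8)
  out <- counts / trend
  med <- stats::median(out)
  if (med > 0) out <- out * stats::median(counts) / med
  out
}

#' Copy-number ratio profile against a reference sample
#'
#' Each bin's normalized depth is divided by the median normalized depth of
#' the reference DNA, so 1.0 is diploid-neutral and the reference sample's
#' own median ratio is exactly 1.
#'
#' @param sample_depths GC-normalized depths of the sample.
#' @param reference_depths GC-normalized depths of the reference (same bins).
#' @param sample_id optional sample label carried in the result.
#' @return list of class `cn_profile` with `sample_id`, `ratio`, `raw`.
#' @export
estimate_copy_ratio <- function(sample_depths, reference_depths,
                                sample_id = NA_character_) {
  stopifnot(length(sample_depths) == length(reference_depths))
  m <- stats::median(reference_depths)
  if (m == 0) stop("median reference depth is zero")
  structure(list(sample_id = sample_id,
                 ratio = as.numeric(sample_depths) / m,
                 raw = as.numeric(sample_depths)),
            class = "cn_profile")
}

#' Depth-distribution QC of a copy-number profile
#'
#' Uneven whole-genome amplification shows up as an overdispersed, skewed
#' normalized-depth distribution; bulk-like samples are symmetric and tight.
#'
#' @param profile a `cn_profile` or numeric vector of ratios.
#' @param skew_threshold absolute moment-skewness above which the profile is
#'   flagged (default 1).
#' @return list: n, mean, variance, skewness, flagged.
#' @export
depth_distribution_qc <- function(profile, skew_threshold = 1) {
  x <- if (inherits(profile, "cn_profile")) profile$ratio else as.numeric(profile)
  if (length(x) == 0) stop("empty profile")
  m <- mean(x); v <- stats::var(x)
  if (length(x) < 2 || is.na(v)) v <- 0
  skew <- if (v == 0) 0 else mean((x - m)^3) / v^1.5
  list(n = length(x), mean = m, variance = v, skewness = skew,
       flagged = abs(skew) > skew_threshold)
}

#' Hierarchical clustering of copy-number profiles into genetic subgroups
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage) of per-bin
#' ratio profiles; the number of clusters is chosen by maximizing the mean
#' silhouette width over k in `[2, min(k_max, n-1)]`.
#'
#' @param profiles numeric matrix, samples in rows, bins in columns (row
#'   names = sample ids), or a list of `cn_profile` objects.
#' @param k_max largest number of clusters considered (default 6).
#' @param linkage hclust method (default "ward.D2").
#' @return list: `labels` (named integer vector), `k`, `silhouette` (mean
#'   width at the chosen k), `hclust` (the dendrogram object).
#' @export
cluster_profiles <- function(profiles, k_max = 6, linkage = "ward.D2") {
  if (is.list(profiles) && !is.matrix(profiles) && !is.data.frame(profiles)) {
    ids <- vapply(profiles, function(p) p$sample_id, character(1))
    profiles <- do.call(rbind, lapply(profiles, function(p) p$ratio))
    rownames(profiles) <- ids
  }
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2) stop("need at least 2 profiles to cluster")
  d <- stats::dist(profiles)
  hc <- stats::hclust(d, method = linkage)
  ks <- seq(2L, max(2L, min(k_max, n - 1L)))
  if (all(d == 0)) {
    warning("all profiles identical; silhouette undefined, returning 2 clusters")
    labels <- stats::cutree(hc, k = 2)
    return(list(labels = labels, k = 2L, silhouette = 0, hclust = hc))
  }
  sil <- vapply(ks, function(k) {
    lab <- stats::cutree(hc, k = k)
    if (length(unique(lab)) < 2) return(-Inf)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  k <- ks[which.max(sil)]
  list(labels = stats::cutree(hc, k = k), k = as.integer(k),
       silhouette = max(sil), hclust = hc)
}
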