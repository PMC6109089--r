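# Joint segmentation of copy-number profiles, trinary/binary event matrices,
# maximum-parsimony tree search, and tree comparison.

#' Joint piecewise-constant segmentation with breakpoints shared across samples
#'
#' Minimizes, independently per chromosome, the penalized least-squares
#' objective `sum_samples sum_bins (y - segment_mean)^2 + gamma * K` over
#' segmentations with `K` breakpoints common to all samples, by exact dynamic
#' programming. Before fitting, each sample is standardized by a robust noise
#' estimate (median absolute first difference / sqrt(2)), so `gamma`
#' penalizes breakpoints on the scale of per-bin noise units, consistent
#' across depths; segment means are reported on the original ratio scale.
#'
#' @param ratios numeric matrix, samples x bins (row names = sample ids).
#' @param bins bin table (chrom, start, end) aligned with the columns.
#' @param gamma per-breakpoint penalty (default 50).
#' @param normalize standardize samples by their noise scale first
#'   (default TRUE; FALSE fits the raw objective, useful for small oracles).
#' @return list of class `segmented_profile`: `segments` (chrom, start, end,
#'   start_bin, end_bin, n_bins), `means` (samples x segments matrix on the
#'   ratio scale), `n_breakpoints`.
#' @export
joint_segmentation <- function(ratios, bins, gamma = 50, normalize = TRUE) {
  ratios <- as.matrix(ratios)
  stopifnot(ncol(ratios) == nrow(bins), gamma > 0)
  y <- ratios
  if (normalize) {
    for (s in seq_len(nrow(y))) {
      sd_s <- stats::mad(diff(y[s, ])) / sqrt(2)
      if (!is.finite(sd_s) || sd_s <= 0) sd_s <- 1
      y[s, ] <- y[s, ] / sd_s
    }
  }
  seg_rows <- list()
  chroms <- unique(bins$chrom)
  for (ch in chroms) {
    idx <- which(bins$chrom == ch)
    n <- length(idx)
    ys <- y[, idx, drop = FALSE]
    cs <- cbind(0, t(apply(ys, 1, cumsum)))          # samples x (n+1)
    cs2 <- cbind(0, t(apply(ys^2, 1, cumsum)))
    segcost <- function(i, j) {                      # bins i..j, 1-based
      len <- j - i + 1
      s1 <- cs[, j + 1] - cs[, i]
      s2 <- cs2[, j + 1] - cs2[, i]
      sum(s2 - s1^2 / len)
    }
    best <- c(0, rep(Inf, n))
    back <- integer(n)
    for (j in seq_len(n)) {
      for (i in seq_len(j)) {
        cand <- best[i] + segcost(i, j) + if (i > 1) gamma else 0
        if (cand < best[j + 1]) { best[j + 1] <- cand; back[j] <- i }
      }
    }
    # backtrack segment starts
    ends <- integer(0); j <- n
    while (j >= 1) { ends <- c(back[j], ends); j <- back[j] - 1L }
    starts_local <- ends
    ends_local <- c(starts_local[-1L] - 1L, n)
    seg_rows[[ch]] <- data.frame(chrom = ch,
                                 start = bins$start[idx[starts_local]],
                                 end = bins$end[idx[ends_local]],
                                 start_bin = idx[starts_local],
                                 end_bin = idx[ends_local],
                                 n_bins = ends_local - starts_local + 1L,
                                 stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL
  means <- matrix(NA_real_, nrow(ratios), nrow(segments),
                  dimnames = list(rownames(ratios), NULL))
  for (k in seq_len(nrow(segments))) {
    cols <- segments$start_bin[k]:segments$end_bin[k]
    means[, k] <- rowMeans(ratios[, cols, drop = FALSE])
  }
  structure(list(segments = segments, means = means,
                 n_breakpoints = nrow(segments) - length(chroms)),
            class = "segmented_profile")
}

#' Trinary CNA event matrix from a segmented profile
#'
#' Per sample, the mean ploidy `m` is the segment-length-weighted mean of its
#' ploidy values (2 x copy ratio, so one copy = 1 ploidy unit). A segment is
#' gain (+1) when its ploidy exceeds `m + event_delta`, loss (-1) below
#' `m - event_delta`, neutral (0) within `m +/- neutral_delta`, and missing
#' (NA) in the ambiguous band between `neutral_delta` and `event_delta`.
#' An all-neutral "normal" root row is appended unless already present.
#'
#' @param segmented a `segmented_profile`.
#' @param event_delta gain/loss threshold in ploidy units (default 0.7).
#' @param neutral_delta neutral band half-width (default 0.5).
#' @param ploidy_scale ploidy per unit copy ratio (default 2: ratio 1 =
#'   diploid).
#' @param add_root append the all-neutral "normal" pseudo-sample
#'   (default TRUE).
#' @return Integer matrix (samples x segments) with values in {-1, 0, 1, NA},
#'   class `event_matrix`, with the segment table in `attr(, "characters")`.
#' @export
trinary_matrix <- function(segmented, event_delta = 0.7, neutral_delta = 0.5,
                           ploidy_scale = 2, add_root = TRUE) {
  stopifnot(neutral_delta < event_delta)
  ploidy <- ploidy_scale * segmented$means
  w <- segmented$segments$end - segmented$segments$start
  m <- as.numeric(ploidy %*% w) / sum(w)
  dev <- sweep(ploidy, 1, m)
  v <- matrix(NA_integer_, nrow(ploidy), ncol(ploidy),
              dimnames = dimnames(ploidy))
  v[dev > event_delta] <- 1L
  v[dev < -event_delta] <- -1L
  v[abs(dev) <= neutral_delta] <- 0L
  if (add_root && !("normal" %in% rownames(v)))
    v <- rbind(v, normal = rep(0L, ncol(v)))
  structure(v, class = c("event_matrix", class(v)),
            characters = segmented$segments, type = "cna")
}

#' Binary SNV event matrix from a consensus table
#'
#' Rows are the included samples (1 = mutated, 0 = not mutated) plus an
#' all-zero "normal" root row; columns are the final consensus loci.
#'
#' @param consensus a `consensus_table`.
#' @param include_samples sample ids to keep (low-purity samples are excluded
#'   upstream); default all.
#' @param add_root append the all-zero "normal" row (default TRUE).
#' @return Integer matrix of class `event_matrix` with locus metadata in
#'   `attr(, "characters")`.
#' @export
binary_snv_matrix <- function(consensus, include_samples = NULL,
                              add_root = TRUE) {
  pres <- consensus$presence
  if (!is.null(include_samples)) {
    stopifnot(all(include_samples %in% colnames(pres)))
    pres <- pres[, include_samples, drop = FALSE]
  }
  m <- t(pres) * 1L
  storage.mode(m) <- "integer"
  if (add_root && !("normal" %in% rownames(m)))
    m <- rbind(m, normal = rep(0L, ncol(m)))
  if (ncol(m) == 0 || all(apply(m, 2, function(col) length(unique(col)) < 2)))
    stop("no informative character: every locus has the same state in all rows")
  structure(m, class = c("event_matrix", class(m)),
            characters = consensus$loci, type = "snv")
}

#' Small-parsimony score of a tree for an event matrix
#'
#' Unit-cost Sankoff (equivalently Fitch for binary characters) dynamic
#' programming over the tree, summed over characters. Missing values are
#' fully ambiguous: the leaf admits every state at no cost, so an
#' all-missing character contributes 0.
#'
#' @param tree an `ape::phylo`; tip labels must all appear as matrix rows.
#' @param matrix an event matrix (rows = taxa, columns = characters; values
#'   are discrete states, NA = missing).
#' @param weights optional per-character multiplicities (default 1).
#' @return Total parsimony score (numeric, integer-valued for unit weights).
#' @export
parsimony_score <- function(tree, matrix, weights = NULL) {
  tips <- tree$tip.label
  if (!all(tips %in% rownames(matrix)))
    stop("tree leaves missing from the matrix: ",
         paste(setdiff(tips, rownames(matrix)), collapse = ", "))
  if (is.null(weights)) weights <- rep(1, ncol(matrix))
  states <- sort(unique(as.vector(matrix[!is.na(matrix)])))
  S <- length(states)
  if (S < 2 || ncol(matrix) == 0) return(0)
  nch <- ncol(matrix)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tips)
  nnode <- max(tr$edge)
  BIG <- 1e9
  # cost[[node]] is an S x nch matrix of minimal subtree costs per state
  cost <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    row <- matrix[tips[i], ]
    ci <- matrix(BIG, S, nch)
    for (s in seq_len(S)) ci[s, is.na(row) | row == states[s]] <- 0
    cost[[i]] <- ci
  }
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; chd <- tr$edge[e, 2]
    if (is.null(cost[[par]])) cost[[par]] <- matrix(0, S, nch)
    child <- cost[[chd]]
    cmin <- apply(child, 2, min)
    # unit-cost simplification: contribution(s) = min(child[s,], cmin + 1)
    contrib <- pmin(child, rep(cmin + 1, each = S))
    cost[[par]] <- cost[[par]] + contrib
  }
  root <- tr$edge[nrow(tr$edge), 1]
  sum(apply(cost[[root]], 2, min) * weights)
}

# collapse identical character patterns into weighted unique columns
compress_characters <- function(matrix) {
  key <- apply(matrix, 2, function(col) paste(ifelse(is.na(col), ".", col),
                                              collapse = ","))
  uq <- !duplicated(key)
  list(matrix = matrix[, uq, drop = FALSE],
       weights = as.numeric(table(key)[key[uq]]))
}

#' Maximum-parsimony tree search over an event matrix
#'
#' For up to `max_exhaustive` taxa, scores every unrooted topology
#' (guaranteed optimum) and returns all co-optimal trees together with their
#' strict consensus; for larger problems, nearest-neighbor-interchange hill
#' climbing from a neighbor-joining start with random restarts. The returned
#' tree is rooted at the outgroup (the normal pseudo-sample) when present.
#'
#' @param matrix an event matrix including the root/normal row.
#' @param max_exhaustive exhaustive-search cutoff on taxa (default 8).
#' @param outgroup row used to root the result (default "normal").
#' @param restarts random restarts for the heuristic path (default 2).
#' @param seed seed for the heuristic path's random restarts.
#' @return list of class `mp_tree`: `tree` (rooted, first optimum), `score`,
#'   `all_optimal` (multiPhylo, exhaustive path only), `consensus` (strict
#'   consensus of co-optimal trees), `method`.
#' @export
search_max_parsimony <- function(matrix, max_exhaustive = 8,
                                 outgroup = "normal", restarts = 2, seed = 1L) {
  taxa <- rownames(matrix)
  n <- length(taxa)
  if (n < 3) stop("need at least 3 rows to build a tree")
  cc <- compress_characters(matrix)
  score_tree <- function(tr) parsimony_score(tr, cc$matrix, cc$weights)

  if (n <= max_exhaustive) {
    topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
    scores <- vapply(topos, score_tree, numeric(1))
    best <- min(scores)
    opt <- topos[scores == best]
    class(opt) <- "multiPhylo"
    cons <- if (length(opt) > 1) ape::consensus(opt, p = 1) else opt[[1]]
    tree <- opt[[1]]
    if (outgroup %in% taxa)
      tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    return(structure(list(tree = tree, score = best, all_optimal = opt,
                          consensus = cons, method = "exhaustive"),
                     class = "mp_tree"))
  }

  # heuristic: NJ start on mean pairwise mismatch, NNI hill climbing
  set.seed(substream_seed(seed, "mp_search"))
  mismatch <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(0)
    mean(a[ok] != b[ok])
  }
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- mismatch(matrix[i, ], matrix[j, ])
  starts <- c(list(ape::unroot(ape::nj(stats::as.dist(d)))),
              replicate(restarts, ape::rtree(n, tip.label = sample(taxa)),
                        simplify = FALSE))
  best_tree <- NULL; best_score <- Inf
  for (tr in starts) {
    tr <- ape::unroot(tr)
    sc <- score_tree(tr)
    repeat {
      nb <- phangorn::nni(tr)
      nb_sc <- vapply(nb, score_tree, numeric(1))
      if (min(nb_sc) < sc) {
        tr <- nb[[which.min(nb_sc)]]; sc <- min(nb_sc)
      } else break
    }
    if (sc < best_score) { best_score <- sc; best_tree <- tr }
  }
  tree <- best_tree
  if (outgroup %in% taxa)
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  structure(list(tree = tree, score = best_score, all_optimal = NULL,
                 consensus = best_tree, method = "nni_hillclimb"),
            class = "mp_tree")
}

#' @export
print.mp_tree <- function(x, ...) {
  cat("maximum-parsimony tree (", x$method, "), score ", x$score, "\n", sep = "")
  print(x$tree)
  invisible(x)
}

#' Robinson-Foulds distance between two trees
#'
#' Standard unrooted RF distance (symmetric difference of the split sets);
#' 0 iff the trees induce identical splits.
#'
#' @param t1,t2 `ape::phylo` trees (or `mp_tree` results) on the same leaves.
#' @return Non-negative integer distance.
#' @export
compare_trees <- function(t1, t2) {
  if (inherits(t1, "mp_tree")) t1 <- t1$tree
  if (inherits(t2, "mp_tree")) t2 <- t2$tree
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2), check.labels = TRUE)
}
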