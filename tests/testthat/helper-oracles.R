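# Independent oracles used across the suite: these re-derive expected values
# by enumeration / brute force, never by calling the code path under test.

# one-sided ("alt greater") p-value of the 2x2 table [[a, d-a], [o, d-o]]
# by direct hypergeometric enumeration
hyper_p_oracle <- function(alt, other, depth) {
  m <- alt + other          # first-column margin
  n2 <- 2 * depth - m       # second-column margin
  k <- depth                # first-row margin
  xs <- max(0, k - n2):min(m, k)
  sum(stats::dhyper(xs[xs >= alt], m, n2, k))
}

# naive double-loop read-in-bin tally
count_bins_oracle <- function(reads, bins) {
  out <- integer(nrow(bins))
  for (i in seq_len(nrow(reads))) {
    for (b in seq_len(nrow(bins))) {
      if (reads$chrom[i] == bins$chrom[b] &&
          reads$pos[i] >= bins$start[b] && reads$pos[i] < bins$end[b]) {
        out[b] <- out[b] + 1L
        break
      }
    }
  }
  out
}

# exhaustive small-parsimony score: minimum over all labelings of the
# internal nodes (and of missing leaves) of the number of state changes
sankoff_oracle <- function(tree, mat) {
  states <- sort(unique(as.vector(mat[!is.na(mat)])))
  tips <- tree$tip.label
  ntip <- length(tips)
  nnode <- max(tree$edge)
  total <- 0
  for (ch in seq_len(ncol(mat))) {
    leaf_state <- mat[tips, ch]
    free <- c(which(is.na(leaf_state)), (ntip + 1):nnode)
    fixed <- stats::setNames(leaf_state, seq_len(ntip))
    grid <- do.call(expand.grid, rep(list(states), length(free)))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      lab <- fixed
      lab[as.character(free)] <- unlist(grid[g, ])
      sc <- sum(lab[as.character(tree$edge[, 1])] !=
                lab[as.character(tree$edge[, 2])])
      best <- min(best, sc)
    }
    total <- total + best
  }
  total
}

# split set of an unrooted tree as canonical strings (smaller side, sorted)
splits_oracle <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (p in pp) {
    side <- sort(labs[p])
    other <- setdiff(tips, side)
    if (length(side) < 2 || length(other) < 2) next  # trivial split
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    out <- c(out, key)
  }
  unique(out)
}

rf_oracle <- function(t1, t2) {
  s1 <- splits_oracle(t1); s2 <- splits_oracle(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# exhaustive shared-breakpoint segmentation on one chromosome:
# minimise sum of squared errors + gamma * n_breakpoints over all 2^(n-1)
# breakpoint subsets
segmentation_oracle <- function(y, gamma) {
  n <- ncol(y)
  sse <- function(i, j) {
    sub <- y[, i:j, drop = FALSE]
    sum((sub - rowMeans(sub))^2)
  }
  best <- Inf; best_starts <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    starts <- c(1L, which(bitwAnd(mask, 2^(0:(n - 2))) > 0) + 1L)
    ends <- c(starts[-1L] - 1L, n)
    obj <- sum(mapply(sse, starts, ends)) + gamma * (length(starts) - 1L)
    if (obj < best) { best <- obj; best_starts <- starts }
  }
  list(objective = best, starts = best_starts)
}
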