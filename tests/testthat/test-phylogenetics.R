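flat_bins <- function(n, width = 1000) {
  data.frame(chrom = "chr1", start = (0:(n - 1)) * width, end = (1:n) * width)
}

test_that("joint segmentation finds shared breakpoints exactly (DP vs oracle)", {
  # all samples flat: no breakpoints at any gamma
  y <- matrix(1, 3, 30, dimnames = list(paste0("S", 1:3), NULL))
  seg <- joint_segmentation(y, flat_bins(30), gamma = 0.1)
  expect_equal(seg$n_breakpoints, 0)

  # one shared step of height 1.0: exactly one breakpoint at the step
  set.seed(2)
  step <- rbind(c(rep(1, 10), rep(2, 10)), c(rep(1, 10), rep(2, 10)),
                c(rep(1, 10), rep(2, 10))) + matrix(rnorm(60, 0, 0.05), 3)
  rownames(step) <- paste0("S", 1:3)
  seg1 <- joint_segmentation(step, flat_bins(20), gamma = 5)
  expect_equal(seg1$n_breakpoints, 1)
  expect_equal(seg1$segments$start_bin, c(1, 11))

  # penalty limit: gamma -> infinity gives a single segment
  seg_inf <- joint_segmentation(step, flat_bins(20), gamma = 1e6)
  expect_equal(seg_inf$n_breakpoints, 0)

  # DP equals exhaustive minimization over all breakpoint subsets
  for (trial in 1:3) {
    set.seed(trial + 40)
    n <- 12
    y <- matrix(rnorm(3 * n, rep(sample(1:3, 3), each = n), 0.3), 3, n,
                byrow = TRUE)
    y[, 7:n] <- y[, 7:n] + rep(c(1, -1, 0.5), n - 6)
    rownames(y) <- paste0("S", 1:3)
    for (gamma in c(0.5, 2, 8)) {
      seg <- joint_segmentation(y, flat_bins(n), gamma = gamma,
                                normalize = FALSE)
      oracle <- segmentation_oracle(y, gamma)
      expect_equal(seg$segments$start_bin, oracle$starts)
    }
  }

  # single bin: one segment, no breakpoints
  one <- joint_segmentation(matrix(1.7, 2, 1), flat_bins(1), gamma = 50)
  expect_equal(nrow(one$segments), 1)
  expect_equal(one$n_breakpoints, 0)
})

test_that("trinary matrix applies the ploidy thresholds literally", {
  # hand-built segmented profile: 4 equal-length segments, known ploidies
  seg <- structure(list(
    segments = data.frame(chrom = "chr1", start = c(0, 10, 20, 30) * 1e5,
                          end = c(10, 20, 30, 40) * 1e5,
                          start_bin = 1:4, end_bin = 1:4, n_bins = 1L),
    means = matrix(c(1.0, 1.0, 1.0, 1.0,          # neutral sample
                     1.3, 1.0, 1.0, 0.7), 2, 4, byrow = TRUE,
                   dimnames = list(c("A", "B"), NULL)),
    n_breakpoints = 3), class = "segmented_profile")
  m <- trinary_matrix(seg)
  expect_equal(unname(m["A", ]), c(0L, 0L, 0L, 0L))        # v = mean exactly
  # sample B: mean ploidy 2, segment ploidies 2.6, 2, 2, 1.4
  expect_equal(unname(m["B", ]), c(NA_integer_, 0L, 0L, NA_integer_))
  expect_true("normal" %in% rownames(m))
  expect_equal(unname(m["normal", ]), rep(0L, 4))

  # full band structure around the sample mean (here mean ploidy = 2):
  # +0.9 gain, +0.6 missing, +0.4 neutral, -0.9 loss
  seg2 <- seg
  seg2$means <- matrix(c(2.9, 2.0, 2.0, 1.1,
                         2.6, 2.0, 2.0, 1.4,
                         2.4, 2.0, 2.0, 1.6) / 2, 3, 4, byrow = TRUE,
                       dimnames = list(c("G", "M", "N"), NULL))
  m2 <- trinary_matrix(seg2, add_root = FALSE)
  expect_equal(unname(m2["G", ]), c(1L, 0L, 0L, -1L))
  expect_equal(unname(m2["M", ]), c(NA_integer_, 0L, 0L, NA_integer_))
  expect_equal(unname(m2["N", ]), c(0L, 0L, 0L, 0L))

  # randomized segments vs cell-wise oracle with length weights
  set.seed(9)
  lens <- sample(1:5, 6, replace = TRUE) * 1e5
  seg3 <- structure(list(
    segments = data.frame(chrom = "chr1", start = cumsum(c(0, head(lens, -1))),
                          end = cumsum(lens), start_bin = 1:6, end_bin = 1:6,
                          n_bins = 1L),
    means = matrix(runif(18, 0.4, 1.6), 3, 6,
                   dimnames = list(c("X", "Y", "Z"), NULL)),
    n_breakpoints = 5), class = "segmented_profile")
  m3 <- trinary_matrix(seg3, add_root = FALSE)
  for (i in 1:3) {
    pl <- 2 * seg3$means[i, ]
    mp <- sum(pl * lens) / sum(lens)
    oracle <- ifelse(pl - mp > 0.7, 1L, ifelse(pl - mp < -0.7, -1L,
              ifelse(abs(pl - mp) <= 0.5, 0L, NA_integer_)))
    expect_equal(unname(m3[i, ]), oracle)
  }
})

test_that("binary SNV matrix mirrors per-sample presence and partitions loci", {
  g <- synthetic_genome(scale = 0.01)
  tr <- simulate_clone_tree(4, 30, 4, g, seed = 37)
  specs <- clean_cohort_specs(4, per_clone = 2)
  chain <- run_snv_chain(tr, specs, error_model(), seed = 37)
  m <- binary_snv_matrix(chain$consensus, include_samples = chain$tumor)
  expect_equal(ncol(m), nrow(chain$consensus$loci))
  expect_equal(unname(m["normal", ]), rep(0L, ncol(m)))
  # matrix equals the truth genotype matrix in the no-noise limit
  for (s in chain$tumor) {
    cl <- specs$clone_id[specs$sample_id == s]
    truth_keys <- with(clone_genotype(tr, cl)$snvs, paste(chrom, pos, alt, sep = ":"))
    expect_setequal(colnames(m)[m[s, ] == 1], truth_keys)
  }
  # category counts partition the loci
  cats <- summarize_categories(chain$consensus)
  expect_equal(sum(cats$count), ncol(m))

  empty <- chain$consensus
  empty$presence <- empty$presence[0, , drop = FALSE]
  empty$loci <- empty$loci[0, ]
  expect_error(binary_snv_matrix(empty), "informative")
})

test_that("parsimony scoring matches exhaustive Sankoff enumeration", {
  # identical rows: zero changes on any topology
  m0 <- matrix(c(1, 0, 1), 4, 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C", "D"), NULL))
  t0 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(parsimony_score(t0, m0), 0)

  # classic 4-taxon example
  m1 <- matrix(c(0, 0, 0, 1, 1, 1, 1, 0), 4, 2,
               dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(parsimony_score(t0, m1), sankoff_oracle(t0, m1))

  # an all-missing character contributes nothing
  m2 <- cbind(m1, NA)
  expect_equal(parsimony_score(t0, m2), parsimony_score(t0, m1))

  # random trinary matrices with missing values, several topologies
  set.seed(19)
  for (trial in 1:4) {
    taxa <- paste0("t", 1:5)
    m <- matrix(sample(c(-1L, 0L, 1L, NA), 5 * 4, replace = TRUE), 5, 4,
                dimnames = list(taxa, NULL))
    tr <- ape::rtree(5, tip.label = sample(taxa))
    expect_equal(parsimony_score(tr, m), sankoff_oracle(tr, m))
  }

  # binary characters: agree with the independent phangorn implementation
  set.seed(23)
  mb <- matrix(sample(0:1, 6 * 12, replace = TRUE), 6, 12,
               dimnames = list(paste0("s", 1:6), NULL))
  tb <- ape::rtree(6, tip.label = paste0("s", 1:6))
  pd <- phangorn::phyDat(mb, type = "USER", levels = 0:1)
  expect_equal(parsimony_score(tb, mb),
               as.numeric(phangorn::parsimony(tb, pd)))

  expect_error(parsimony_score(ape::rtree(3, tip.label = c("A", "B", "zz")), m1),
               "missing from the matrix")
})

test_that("exhaustive search returns the optimum and recovers known trees", {
  # star-uninformative matrix: any topology, score 0
  m0 <- matrix(1L, 4, 5, dimnames = list(c("A", "B", "C", "D"), NULL))
  mp0 <- search_max_parsimony(m0)
  expect_equal(mp0$score, 0)

  # the exhaustive optimum is no worse than every enumerated topology
  set.seed(31)
  m <- matrix(sample(0:1, 6 * 15, replace = TRUE), 6, 15,
              dimnames = list(paste0("s", 1:6), NULL))
  mp <- search_max_parsimony(m)
  topos <- phangorn::allTrees(6, rooted = FALSE, tip.label = paste0("s", 1:6))
  scores <- vapply(topos, function(tr) parsimony_score(tr, m), numeric(1))
  expect_equal(mp$score, min(scores))

  # known 6-leaf clone tree, no noise: recovered with RF = 0
  rec <- recovery_replicate(seed = 51)
  expect_equal(rec$rf_snv, 0)

  expect_error(search_max_parsimony(m0[1:2, ]), "at least 3")
})

test_that("heuristic search never ends above its neighbor-joining start", {
  set.seed(41)
  taxa <- paste0("s", 1:10)
  m <- matrix(sample(0:1, 10 * 25, replace = TRUE), 10, 25,
              dimnames = list(taxa, NULL))
  mp <- search_max_parsimony(m, max_exhaustive = 8)
  expect_equal(mp$method, "nni_hillclimb")
  mismatch <- function(a, b) mean(a != b)
  d <- outer(seq_len(10), seq_len(10),
             Vectorize(function(i, j) mismatch(m[i, ], m[j, ])))
  dimnames(d) <- list(taxa, taxa)
  nj_score <- parsimony_score(ape::unroot(ape::nj(as.dist(d))), m)
  expect_lte(mp$score, nj_score)
})

test_that("Robinson-Foulds distance equals split-set symmetric difference", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(compare_trees(t1, t1), 0)

  # one NNI move on 4 taxa: distance 2
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(compare_trees(t1, t2), 2)
  expect_equal(compare_trees(t1, t2), rf_oracle(t1, t2))

  # caterpillar vs balanced 6-leaf vs brute-force split enumeration
  cat6 <- ape::read.tree(text = "(A,(B,(C,(D,(E,F)))));")
  bal6 <- ape::read.tree(text = "((A,(B,C)),(D,(E,F)));")
  expect_equal(compare_trees(cat6, bal6), rf_oracle(cat6, bal6))

  expect_error(compare_trees(t1, cat6), "leaf sets")
})

test_that("excluding a low-purity sample preserves the remaining splits", {
  rec <- recovery_replicate(seed = 61, n_clones = 5, n_snvs = 50, n_cnas = 10)
  m <- binary_snv_matrix(rec$consensus,
                         include_samples = paste0("S", 1:5))
  full <- search_max_parsimony(m)
  drop1 <- search_max_parsimony(m[setdiff(rownames(m), "S5"), ])
  pruned <- ape::drop.tip(full$consensus, "S5")
  expect_equal(compare_trees(pruned, drop1$consensus), 0)
})
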