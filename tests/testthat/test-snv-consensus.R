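mk_calls <- function(caller, loci, sample = "S1") {
  data.frame(caller_id = caller, sample_id = sample,
             chrom = loci$chrom, pos = loci$pos, ref = loci$ref,
             alt = loci$alt, alt_depth = 10L, total_depth = 100L,
             stringsAsFactors = FALSE)
}

rand_loci <- function(n, seed) {
  set.seed(seed)
  data.frame(chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
             pos = sample.int(1e6, n), ref = "A",
             alt = sample(c("C", "G", "T"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("intra-sample double-calling keeps loci seen by >= 2 of 3 callers", {
  loci <- rand_loci(6, 1)
  cs <- rbind(mk_calls("gatk", loci[1:4, ]),
              mk_calls("varscan", loci[c(1, 2, 5), ]),
              mk_calls("mutect", loci[6, ]))
  dc <- intra_sample_double_called(cs)
  expect_setequal(paste(dc$chrom, dc$pos, dc$alt),
                  paste(loci$chrom[1:2], loci$pos[1:2], loci$alt[1:2]))
  expect_true(all(dc$n_callers == 2))

  # a locus seen by one caller only is excluded
  expect_false(any(dc$pos == loci$pos[6]))

  # random injection vs set-algebra oracle
  pool <- rand_loci(100, 2)
  idx <- lapply(1:3, function(k) sort(sample.int(100, 60)))
  cs2 <- do.call(rbind, Map(function(k, i)
    mk_calls(c("gatk", "varscan", "mutect")[k], pool[i, ]), 1:3, idx))
  dc2 <- intra_sample_double_called(cs2)
  votes <- table(unlist(lapply(idx, unique)))
  expect_setequal(paste(dc2$chrom, dc2$pos, dc2$alt),
                  paste(pool$chrom, pool$pos, pool$alt)[
                    as.integer(names(votes)[votes >= 2])])

  expect_error(intra_sample_double_called(rbind(mk_calls("gatk", loci),
                                                mk_calls("gatk", loci),
                                                mk_calls("mutect", loci))),
               "3 distinct callers")
})

test_that("germline removal is an exact set difference on (chrom,pos,alt)", {
  loci <- rand_loci(20, 3)
  expect_identical(remove_germline(loci, loci[0, ]), loci)
  expect_equal(nrow(remove_germline(loci, loci)), 0)
  norm <- loci[sample.int(20, 8), ]
  out <- remove_germline(loci, norm)
  key <- function(d) paste(d$chrom, d$pos, d$alt)
  expect_setequal(key(out), setdiff(key(loci), key(norm)))
})

test_that("confident sites require double-calling in >= 2 samples", {
  loci <- rand_loci(10, 4)
  dc <- list(A = loci[1:6, ], B = loci[4:8, ], C = loci[9, ])
  conf <- confident_sites(dc)
  key <- function(d) paste(d$chrom, d$pos, d$alt)
  expect_setequal(key(conf), key(loci[4:6, ]))
  expect_false(any(key(conf) %in% key(loci[c(1:3, 9:10), ])))
  expect_error(confident_sites(dc["A"]), "at least 2")
})

test_that("Fisher rescue matches the hypergeometric oracle and gates on callers", {
  row <- data.frame(chrom = "chr1", pos = 100, ref = "A",
                    A = 88, C = 12, G = 0, T = 0)
  rs <- fisher_rescue(row, "C", any_caller_called = TRUE)
  expect_true(rs$present)
  expect_equal(rs$p_value, hyper_p_oracle(12, 0, 100), tolerance = 1e-12)
  expect_lt(rs$p_value, 1e-3)

  # gate: without a caller the variant stays absent no matter the counts
  expect_false(fisher_rescue(row, "C", any_caller_called = FALSE)$present)

  # symmetric table: no evidence the alt outgrows the comparator base
  # (one-sided p includes the observed table, ~0.69 here)
  sym <- data.frame(chrom = "chr1", pos = 1, ref = "A", A = 96, C = 2, G = 2, T = 0)
  rs2 <- fisher_rescue(sym, "C", any_caller_called = TRUE)
  expect_equal(rs2$p_value, hyper_p_oracle(2, 2, 100), tolerance = 1e-9)
  expect_gt(rs2$p_value, 0.5)
  expect_false(rs2$present)

  # the comparator is the larger of the two other non-reference bases
  mix <- data.frame(chrom = "chr1", pos = 2, ref = "A", A = 80, C = 12, G = 8, T = 0)
  expect_equal(fisher_rescue(mix, "C", TRUE)$other_max, 8)
  expect_equal(fisher_rescue(mix, "C", TRUE)$p_value,
               hyper_p_oracle(12, 8, 100), tolerance = 1e-12)

  expect_error(fisher_rescue(row, "A", TRUE), "reference")
})

test_that("the consensus chain reproduces simulator truth without noise", {
  g <- synthetic_genome(scale = 0.01)
  tr <- simulate_clone_tree(4, 40, 4, g, seed = 13)
  specs <- clean_cohort_specs(4, purity = 1, depth = 300, per_clone = 2)
  chain <- run_snv_chain(tr, specs, error_model(), seed = 13)
  cons <- chain$consensus

  # every true locus present in exactly the samples whose clone carries it
  for (s in chain$tumor) {
    cl <- specs$clone_id[specs$sample_id == s]
    truth_keys <- with(clone_genotype(tr, cl)$snvs, paste(chrom, pos, alt, sep = ":"))
    expect_setequal(rownames(cons$presence)[cons$presence[, s]], truth_keys)
  }
  expect_equal(nrow(cons$loci), 40)
  expect_true(all(cons$loci$category %in%
                  c("common", "primary_only", "ascites_only")))
})

test_that("double-call and confident-site filters suppress the two error modes", {
  g <- synthetic_genome(scale = 0.01)
  tr <- simulate_clone_tree(4, 40, 4, g, seed = 17)
  specs <- clean_cohort_specs(4, purity = 1, depth = 300, per_clone = 2)

  # caller-private NGS FPs only: no FP locus coincides across callers, so
  # the double-call filter removes them all
  chain_ngs <- run_snv_chain(tr, specs, error_model(ngs_fp_rate = 0.15),
                             seed = 17)
  fp_keys <- with(chain_ngs$calls[chain_ngs$calls$origin == "ngs_fp", ],
                  paste(chrom, pos, alt, sep = ":"))
  expect_gt(length(fp_keys), 0)
  expect_false(any(rownames(chain_ngs$consensus$presence) %in% fp_keys))

  # sample-private WGA FPs only: no locus coincides across samples, so the
  # confident-site filter removes them all
  chain_wga <- run_snv_chain(tr, specs, error_model(wga_fp_rate = 0.15),
                             seed = 17)
  wga_keys <- with(chain_wga$calls[chain_wga$calls$origin == "wga_fp", ],
                   paste(chrom, pos, alt, sep = ":"))
  expect_gt(length(wga_keys), 0)
  expect_false(any(rownames(chain_wga$consensus$presence) %in% wga_keys))

  # recall stays 1 in both cases
  expect_equal(nrow(chain_ngs$consensus$loci), 40)
  expect_equal(nrow(chain_wga$consensus$loci), 40)
})

test_that("consensus is monotone in alpha and in added calls", {
  g <- synthetic_genome(scale = 0.01)
  tr <- simulate_clone_tree(3, 30, 3, g, seed = 23)
  specs <- clean_cohort_specs(3, purity = 0.5, depth = 60)
  strict <- run_snv_chain(tr, specs, error_model(fn_rate = 0.3), seed = 23,
                          config = consensus_config(fisher_alpha = 1e-6))
  loose <- run_snv_chain(tr, specs, error_model(fn_rate = 0.3), seed = 23,
                         config = consensus_config(fisher_alpha = 1e-2))
  expect_true(all(strict$consensus$presence <= loose$consensus$presence))

  # adding a caller's calls never shrinks the double-called set
  loci <- rand_loci(30, 31)
  base <- rbind(mk_calls("gatk", loci[1:10, ]), mk_calls("varscan", loci[5:20, ]),
                mk_calls("mutect", loci[1:3, ]))
  more <- rbind(base, mk_calls("mutect", loci[21:30, ]))
  more <- more[!duplicated(paste(more$caller_id, more$chrom, more$pos, more$alt)), ]
  key <- function(d) paste(d$chrom, d$pos, d$alt)
  expect_true(all(key(intra_sample_double_called(base)) %in%
                  key(intra_sample_double_called(more))))

  # final present loci are a subset of the union of all caller calls
  ckey <- paste(loose$calls$chrom, loose$calls$pos, loose$calls$alt, sep = ":")
  expect_true(all(rownames(loose$consensus$presence)[
    rowSums(loose$consensus$presence) > 0] %in% ckey))
})

test_that("category arithmetic turns counts into percentages of the total", {
  s <- summarize_categories(c(common = 66, primary_only = 61, ascites_only = 44))
  expect_equal(attr(s, "total"), 171)
  expect_equal(s$percent, c(38.6, 35.7, 25.7))
  expect_equal(sum(s$percent), 100, tolerance = 0.15)
})
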