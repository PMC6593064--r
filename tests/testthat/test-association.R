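rs4937333 <- genotype_table("rs4937333", c("CC", "CT", "TT"),
                            c(21, 24, 21), c(15, 24, 3))

test_that("allele counts derive as 2*hom + het per group", {
  am <- alleles_from_genotypes(rs4937333)
  expect_equal(am["C", ], c(case = 66L, control = 54L))
  expect_equal(am["T", ], c(case = 66L, control = 30L))

  # all-homozygous-reference table: zero alt alleles in both groups
  mono_ish <- genotype_table("s", c("GG", "GA", "AA"), c(10, 0, 0),
                             c(7, 0, 0))
  expect_equal(unname(alleles_from_genotypes(mono_ish)["A", ]), c(0L, 0L))

  # pure heterozygotes split alleles evenly
  het <- genotype_table("s", c("CC", "CT", "TT"), c(0, 10, 0), c(0, 10, 0))
  expect_equal(unname(alleles_from_genotypes(het)["C", ]), c(10L, 10L))
  expect_equal(unname(alleles_from_genotypes(het)["T", ]), c(10L, 10L))
})

test_that("genotype_table validates structure", {
  expect_error(genotype_table("s", c("CC", "CT"), c(1, 2), c(1, 2)),
               "3 genotype")
  expect_error(genotype_table("s", c("CC", "CT", "GG"), c(1, 1, 1),
                              c(1, 1, 1)), "alleles")
  expect_error(genotype_table("s", c("CT", "CC", "TT"), c(1, 1, 1),
                              c(1, 1, 1)), "hom-ref")
  expect_error(genotype_table("s", c("CC", "CT", "TT"), c(1, -1, 1),
                              c(1, 1, 1)), "nonnegative")
})

test_that("Woolf odds-ratio intervals reproduce the published values", {
  published <- list(
    list(cells = c(66, 30, 66, 54), or = 1.800, lo = 1.026, hi = 3.157),
    list(cells = c(21, 3, 21, 15), or = 5.000, lo = 1.259, hi = 19.860),
    list(cells = c(24, 24, 21, 15), or = 0.714, lo = 0.299, hi = 1.707),
    list(cells = c(18, 9, 39, 30), or = 1.538, lo = 0.606, hi = 3.903),
    list(cells = c(9, 3, 39, 30), or = 2.308, lo = 0.574, hi = 9.271),
    list(cells = c(36, 15, 96, 69), or = 1.725, lo = 0.876, hi = 3.395))
  for (case in published) {
    r <- odds_ratio_ci(do.call(contingency_2x2, as.list(case$cells)))
    expect_equal(floor(r$odds_ratio * 1000 + 0.5) / 1000, case$or)
    expect_equal(floor(r$ci_low * 1000 + 0.5) / 1000, case$lo)
    expect_equal(floor(r$ci_high * 1000 + 0.5) / 1000, case$hi)
    expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  }
})

test_that("symmetric tables give OR 1 with a CI straddling 1", {
  r <- odds_ratio_ci(contingency_2x2(10, 10, 10, 10))
  expect_equal(r$odds_ratio, 1)
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)
})

test_that("zero cells leave the CI undefined unless Haldane is requested", {
  t0 <- contingency_2x2(5, 0, 3, 7)
  r <- odds_ratio_ci(t0)
  expect_false(r$defined)
  expect_true(is.na(r$odds_ratio))
  rh <- odds_ratio_ci(t0, haldane = TRUE)
  expect_true(rh$defined)
  expect_equal(rh$odds_ratio, (5.5 * 7.5) / (0.5 * 3.5))
})

test_that("Pearson chi-square matches its closed form and stats::chisq.test", {
  t1 <- contingency_2x2(66, 30, 66, 54)
  r1 <- chisq_test_2x2(t1)
  expect_equal(r1$statistic, 4.2428, tolerance = 1e-4)
  expect_equal(r1$p, pchisq(r1$statistic, 1, lower.tail = FALSE))

  t2 <- contingency_2x2(21, 3, 21, 15)
  expect_equal(chisq_test_2x2(t2)$statistic, 5.8333, tolerance = 1e-4)

  # proportional table: no association
  r0 <- chisq_test_2x2(contingency_2x2(20, 10, 40, 20))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  # cross-check statistic and continuity correction against stats::
  set.seed(11)
  for (k in 1:25) {
    cells <- rbinom(4, 30, 0.5) + 1L
    m <- matrix(cells, 2)
    t3 <- contingency_2x2(cells[1], cells[3], cells[2], cells[4])
    expect_equal(chisq_test_2x2(t3)$statistic,
                 unname(chisq.test(m, correct = FALSE)$statistic))
    expect_equal(chisq_test_2x2(t3, continuity = TRUE)$statistic,
                 unname(chisq.test(m, correct = TRUE)$statistic))
  }

  expect_warning(r <- chisq_test_2x2(contingency_2x2(0, 0, 5, 5)),
                 "zero margin")
  expect_false(r$defined)
})

test_that("Fisher exact equals brute-force hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(contingency_2x2(21, 3, 21, 15)),
               oracle_fisher(21, 3, 21, 15))
  # degenerate table: only the two extreme tables carry its probability
  expect_equal(fisher_exact_2x2(contingency_2x2(5, 0, 0, 5)),
               2 / choose(10, 5))
  expect_equal(fisher_exact_2x2(contingency_2x2(10, 10, 10, 10)), 1)
  set.seed(7)
  for (k in 1:50) {
    cells <- as.integer(rmultinom(1, sample(10:60, 1), runif(4, 0.1, 1)))
    if (sum(cells) == 0) next
    t2 <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(fisher_exact_2x2(t2),
                 do.call(oracle_fisher, as.list(cells)))
    expect_equal(fisher_exact_2x2(t2),
                 fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("case/control and exposure swaps invert the OR and keep p-values", {
  set.seed(21)
  for (k in 1:20) {
    cells <- rbinom(4, 40, 0.4) + 1L
    t0 <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    tc <- contingency_2x2(cells[2], cells[1], cells[4], cells[3])  # col swap
    tr <- contingency_2x2(cells[3], cells[4], cells[1], cells[2])  # row swap
    r0 <- odds_ratio_ci(t0); rc <- odds_ratio_ci(tc); rr <- odds_ratio_ci(tr)
    expect_equal(rc$odds_ratio, 1 / r0$odds_ratio)
    expect_equal(rr$odds_ratio, 1 / r0$odds_ratio)
    expect_equal(rc$ci_low, 1 / r0$ci_high)
    expect_equal(rc$ci_high, 1 / r0$ci_low)
    expect_equal(chisq_test_2x2(tc)$p, chisq_test_2x2(t0)$p)
    expect_equal(fisher_exact_2x2(tc), fisher_exact_2x2(t0))
    expect_equal(fisher_exact_2x2(tr), fisher_exact_2x2(t0))
  }
})

test_that("HWE chi-square behaves on published counts and closed forms", {
  r <- hwe_test(c(15, 24, 3), "controls")
  expect_equal(r$chi2, 2.5096, tolerance = 1e-4)
  expect_gt(r$p, 0.05)

  expect_equal(hwe_test(c(25, 50, 25))$chi2, 0)
  # no heterozygotes at p = 0.5: chi2 equals the sample size
  expect_equal(hwe_test(c(50, 0, 50))$chi2, 100)

  mono <- hwe_test(c(40, 0, 0))
  expect_false(mono$applicable)
  expect_true(is.na(mono$chi2))

  # invariant under relabeling which allele is major
  set.seed(5)
  for (k in 1:20) {
    g <- as.integer(rmultinom(1, 100, c(0.3, 0.5, 0.2)))
    expect_equal(hwe_test(g)$chi2, hwe_test(rev(g))$chi2)
  }
})

test_that("build_table1 reproduces the published association table", {
  counts <- read.delim(system.file("extdata", "table1_counts.tsv",
                                   package = "seedshift"),
                       comment.char = "#", stringsAsFactors = FALSE)
  rep <- build_table1(counts = counts)
  mono <- vapply(rep$snps, function(s) isTRUE(s$monomorphic), logical(1))
  expect_equal(sum(mono), 6L)
  expect_setequal(names(rep$snps)[!mono], c("rs1128334", "rs4937333"))

  rs <- rep$snps$rs4937333
  expect_equal(rs$allele_or$odds_ratio, 1.8)
  expect_equal(rs$genotype_or$hom$odds_ratio, 5)
  expect_equal(rs$genotype_or$het$odds_ratio, 24 * 15 / (24 * 21))
  expect_equal(rs$table$genotype_labels, c("CC", "CT", "TT"))

  fmt <- rep$formatted
  row_t <- fmt[fmt$snp_id == "rs4937333" & fmt$level == "T", ]
  expect_equal(row_t$odds_ratio, "1.800")
  expect_equal(row_t$ci95, "1.026-3.157")
  expect_equal(row_t$case, "66 (50.0)")
  # monomorphic SNPs print dashes
  row_m <- fmt[fmt$snp_id == "rs1128355", ]
  expect_equal(row_m$odds_ratio, "-")
  expect_equal(row_m$case, "66 (100)")
})

test_that("per-sample records round-trip to the same table as counts", {
  counts <- read.delim(system.file("extdata", "table1_counts.tsv",
                                   package = "seedshift"),
                       comment.char = "#", stringsAsFactors = FALSE)
  sub <- counts[counts$snp_id == "rs4937333", ]
  records <- data.frame(
    sample_id = sprintf("S%03d", 1:108),
    group = c(rep("case", 66), rep("control", 42)),
    rs4937333 = c(rep(sub$genotype, sub$case_n),
                  rep(sub$genotype, sub$control_n)),
    stringsAsFactors = FALSE)
  # unordered calls: scramble some to the reversed spelling
  records$rs4937333[records$rs4937333 == "CT"][1:5] <- "TC"
  rep1 <- build_table1(records = records)
  expect_equal(rep1$snps$rs4937333$allele_or$odds_ratio, 1.8)
  expect_equal(rep1$snps$rs4937333$table$case_counts, c(21L, 24L, 21L))

  # missing calls are dropped pairwise with a message
  records$rs4937333[1] <- NA
  expect_message(rep2 <- build_table1(records = records), "excluded")
  expect_equal(sum(rep2$snps$rs4937333$table$case_counts), 65L)

  # a third allele is a validation error naming samples
  records$rs4937333[2] <- "AG"
  expect_error(build_table1(records = records), "more than two alleles")
})

test_that("empty record sets yield an empty report without crashing", {
  rep <- build_table1(records = data.frame(sample_id = character(0),
                                           group = character(0)))
  expect_length(rep$snps, 0)
})
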