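test_that("an unstructured background gives a pure-duplex diagram", {
  mir <- nuc_sequence("UCACAGUGGCUAAGUUCUGCAC", id = "mir")
  site_seq <- as.character(revcomp(substr(mir, 2, 8)))
  win <- paste0(strrep("A", 26), site_seq, "A", strrep("A", 25))
  d <- energy_diagram(win, c(26, 34), mir)
  expect_equal(d$E_target, 0)       # poly-A background cannot fold
  expect_equal(d$dE_a, 0)
  expect_lt(d$dE_b, 0)              # binding is favorable
  expect_equal(d$dE_b, d$E_duplex)
  # the three-state identity holds exactly
  expect_equal(d$dE_b - d$dE_a, d$E_duplex)
  expect_equal(d$E_complex, d$E_intermediate + d$E_duplex)
})

test_that("a site sequestered in a hairpin costs activation energy", {
  # 24-nt constructed hairpin: the site lies in the 5' arm of a stem
  mir <- nuc_sequence("UCACAGUGGCUAAGUUCUGCAC", id = "mir")
  site_seq <- as.character(revcomp(substr(mir, 2, 8)))   # 7 nt
  win <- paste0("AAA", site_seq, "AAAA", as.character(revcomp(site_seq)),
                "AAA")
  expect_lt(mfe_fold(win)$energy, 0)   # the stem really forms
  d <- energy_diagram(win, c(3, 10), mir)
  expect_gt(d$dE_a, 0)
  expect_equal(d$dE_a, d$E_intermediate - d$E_target)
  # verified against constrained enumeration on this small window
  blocked <- logical(nchar(win)); blocked[4:10] <- TRUE
  expect_equal(d$E_intermediate,
               oracle_mfe(win, blocked = blocked)$energy, tolerance = 1e-9)
  expect_equal(d$E_target, oracle_mfe(win)$energy, tolerance = 1e-9)
})

test_that("a zero-length site yields the degenerate diagram", {
  d <- energy_diagram("GGGAAACCC", c(4, 4), "UCACAGUGGCUAAGUUCUGCAC")
  expect_equal(d$dE_a, 0)
  expect_equal(d$dE_b, 0)
  expect_equal(d$E_complex, d$E_target)
  expect_error(energy_diagram("GGGAAACCC", c(4, 99), "UCACAGUGG"),
               "outside the window")
})

test_that("seed mismatches never strengthen binding on open backgrounds", {
  # replace one WC seed pair with a non-pairing base: dE_b cannot decrease
  set.seed(41)
  for (k in 1:10) {
    mir <- nuc_sequence(rand_rna(20), id = "m")
    site <- strsplit(as.character(revcomp(substr(mir, 2, 8))), "")[[1]]
    win_perfect <- paste0(strrep("A", 20), paste(site, collapse = ""), "A",
                          strrep("A", 20))
    pos <- sample(1:7, 1)
    m_base <- substr(mir, 9 - pos, 9 - pos)
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    non_pairing <- setdiff(c("A", "C", "G", "U"),
                           c(comp[[m_base]],
                             if (m_base == "G") "U",
                             if (m_base == "U") "G"))
    site[pos] <- non_pairing[1]
    win_mut <- paste0(strrep("A", 20), paste(site, collapse = ""), "A",
                      strrep("A", 20))
    d_perfect <- energy_diagram(win_perfect, c(20, 28), mir)
    d_mut <- energy_diagram(win_mut, c(20, 28), mir)
    expect_gte(d_mut$dE_b, d_perfect$dE_b - 1e-9)
  }
})

test_that("compare_alleles is antisymmetric under allele swap", {
  for (s in c(3, 14, 25)) {
    w <- gen_snp_window(seed = s)
    cmp <- compare_alleles(w$window_ref, w$snp, w$mirna)
    expect_true(cmp$informative)
    # identity dE_b - dE_a = E_duplex holds for both alleles
    expect_equal(cmp$alt$dE_b - cmp$alt$dE_a, cmp$alt$E_duplex)
    expect_equal(cmp$ref$dE_b - cmp$ref$dE_a, cmp$ref$E_duplex)
    # swap ref/alt: delta negates, favored allele flips
    snp_sw <- snp_variant(w$snp$snp_id, w$snp$position,
                          w$snp$alt_allele, w$snp$ref_allele,
                          window = w$window_alt)
    cmp_sw <- compare_alleles(w$window_alt, snp_sw, w$mirna)
    expect_equal(cmp_sw$delta_binding, -cmp$delta_binding)
    if (cmp$favored_allele == "alt")
      expect_equal(cmp_sw$favored_allele, "ref")
  }
})

test_that("a SNP outside any site leaves binding unchanged", {
  w <- gen_snp_window(seed = 8)
  # move the SNP to the first window position, far from the embedded site
  b0 <- substr(as.character(w$window_ref), 1, 1)
  alt0 <- setdiff(c("A", "C", "G", "U"), b0)[1]
  snp_far <- snp_variant("far", 0L, b0, alt0, window = w$window_ref)
  cmp <- compare_alleles(w$window_ref, snp_far, w$mirna)
  # neither allele has a site overlapping position 0 (checked, not assumed)
  if (!cmp$informative) {
    expect_equal(cmp$delta_binding, 0)
    expect_equal(cmp$favored_allele, "tie")
  }
})

test_that("the energy model loader validates its tables", {
  stack_f <- system.file("extdata", "nn_stacks.tsv", package = "seedshift")
  loop_f <- system.file("extdata", "loop_penalties.tsv",
                        package = "seedshift")
  m <- energy_model(stack_f, loop_f)
  expect_s3_class(m, "energy_model")
  expect_equal(m$stack["GC", "GC"], -3.26)
  expect_equal(m$hairpin[3], 5.4)
  # loop penalties extrapolate and never decrease beyond the table
  expect_true(all(diff(m$hairpin[9:200]) >= 0))

  broken <- read.delim(stack_f, comment.char = "#")
  broken$dG[1] <- broken$dG[1] + 1   # break strand-flip symmetry
  tmp <- tempfile(fileext = ".tsv")
  write.table(broken, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(energy_model(tmp, loop_f), "symmetry")
})
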