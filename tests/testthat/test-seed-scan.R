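# a fixed miRNA whose seed revcomp is used to build windows by construction
MIR <- nuc_sequence("UCACAGUGGCUAAGUUCUGCAC", id = "mir_test")

seed_rc <- function(mir, from, to) as.character(revcomp(substr(mir, from, to)))

test_that("constructed sites are found with the right class and interval", {
  # flanks use U, which neither pairs m8 (= G here) nor supplies an A1
  # 8mer: seed revcomp plus the A opposite miRNA position 1
  win8 <- paste0(strrep("U", 10), seed_rc(MIR, 2, 8), "A", strrep("U", 10))
  hits <- scan_seed_sites(win8, MIR)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$seed_class, "8mer")
  expect_equal(c(hits$start, hits$end), c(10L, 18L))
  # the matched residues are the exact reverse complement of m2-m8
  expect_equal(substr(win8, hits$start + 1, hits$end - 1), seed_rc(MIR, 2, 8))

  # 7mer-m8: same core, no downstream A
  win7m8 <- paste0(strrep("U", 10), seed_rc(MIR, 2, 8), strrep("U", 10))
  h <- scan_seed_sites(win7m8, MIR)
  expect_equal(h$seed_class, "7mer-m8")
  expect_equal(c(h$start, h$end), c(10L, 17L))

  # 7mer-A1: core + A, no m8 match
  win7a1 <- paste0(strrep("U", 10), seed_rc(MIR, 2, 7), "A", strrep("U", 10))
  h <- scan_seed_sites(win7a1, MIR)
  expect_equal(h$seed_class, "7mer-A1")
  expect_equal(c(h$start, h$end), c(10L, 17L))

  # 6mer: bare core
  win6 <- paste0(strrep("U", 10), seed_rc(MIR, 2, 7), strrep("U", 10))
  h <- scan_seed_sites(win6, MIR)
  expect_equal(h$seed_class, "6mer")
  expect_equal(c(h$start, h$end), c(10L, 16L))
})

test_that("windows without complementarity yield no sites", {
  # a window of U cannot match a seed revcomp containing anything but A
  expect_equal(nrow(scan_seed_sites(strrep("U", 30), MIR)), 0L)
  expect_warning(h <- scan_seed_sites("ACGU", MIR), "shorter than 6")
  expect_equal(nrow(h), 0L)
})

test_that("disjoint sites are reported in coordinate order", {
  core <- seed_rc(MIR, 2, 8)
  win <- paste0("CC", core, strrep("C", 6), core, "CC")
  h <- scan_seed_sites(win, MIR)
  expect_equal(nrow(h), 2L)
  expect_true(all(diff(h$start) > 0))
  expect_true(all(h$seed_class == "7mer-m8"))
  # scanning is deterministic
  expect_identical(h, scan_seed_sites(win, MIR))
})

test_that("G:U wobble counts as a match only when allowed", {
  core <- seed_rc(MIR, 2, 7)
  ch <- strsplit(core, "")[[1]]
  # replace one WC partner by the wobble partner where possible
  i <- which(ch %in% c("C", "A"))[1]
  skip_if(is.na(i))
  ch[i] <- if (ch[i] == "C") "U" else "G"
  # wobble target base: U pairs G (was C:G), G pairs U (was A:U)
  win <- paste0(strrep("C", 8), paste(ch, collapse = ""), strrep("C", 8))
  expect_equal(nrow(scan_seed_sites(win, MIR)), 0L)
  expect_gte(nrow(scan_seed_sites(win, MIR, allow_wobble = TRUE)), 1L)
})

test_that("classify_snp_effect labels allele transitions", {
  core <- seed_rc(MIR, 2, 8)                     # 7 nt matching m8..m2
  core_ch <- strsplit(core, "")[[1]]
  # ref breaks position 4 of the core; alt restores it
  broken <- core_ch
  alt_base <- core_ch[4]
  broken[4] <- if (alt_base == "A") "C" else "A"
  win_ref <- paste0(strrep("C", 10), paste(broken, collapse = ""),
                    strrep("C", 10))
  snp <- snp_variant("rs_test", 13L, broken[4], alt_base,
                     window = nuc_sequence(win_ref))
  res <- classify_snp_effect(win_ref, snp, MIR)
  expect_equal(res$effect, "site_created")
  expect_true(res$snp_in_seed)
  expect_equal(res$ref_site$seed_class, "none")
  expect_equal(res$alt_site$seed_class, "7mer-m8")

  # swapping ref and alt maps site_created to site_destroyed
  win_alt <- as.character(apply_alt_allele(nuc_sequence(win_ref), snp))
  snp_sw <- snp_variant("rs_test", 13L, alt_base, broken[4],
                        window = nuc_sequence(win_alt))
  res_sw <- classify_snp_effect(win_alt, snp_sw, MIR)
  expect_equal(res_sw$effect, "site_destroyed")

  # SNP outside any site: no_change, not in seed
  far <- snp_variant("rs_far", 0L, substr(win_ref, 1, 1), "A")
  res_far <- classify_snp_effect(win_ref, far, MIR)
  expect_equal(res_far$effect, "no_change")
  expect_false(res_far$snp_in_seed)
})

test_that("class transitions are graded, not just created/destroyed", {
  # ref has the bare 6mer; alt adds the m8 match one base upstream
  core6 <- seed_rc(MIR, 2, 7)
  m8_target <- substr(seed_rc(MIR, 2, 8), 1, 1)
  ref_base <- if (m8_target == "A") "C" else "A"
  win_ref <- paste0(strrep("C", 9), ref_base, core6, strrep("C", 9))
  snp <- snp_variant("rs_up", 9L, ref_base, m8_target,
                     window = nuc_sequence(win_ref))
  res <- classify_snp_effect(win_ref, snp, MIR)
  expect_equal(res$ref_site$seed_class, "6mer")
  expect_equal(res$alt_site$seed_class, "7mer-m8")
  expect_equal(res$effect, "class_up")

  # and the reverse direction is class_down (antisymmetry)
  win_alt <- as.character(apply_alt_allele(nuc_sequence(win_ref), snp))
  snp_sw <- snp_variant("rs_up", 9L, m8_target, ref_base,
                        window = nuc_sequence(win_alt))
  expect_equal(classify_snp_effect(win_alt, snp_sw, MIR)$effect,
               "class_down")
})

test_that("every reported interval reverse-complements the seed exactly", {
  set.seed(31)
  n_hits <- 0L
  for (k in 1:25) {
    mir <- nuc_sequence(rand_rna(21), id = "m")
    win <- rand_rna(80)
    if (k %% 2 == 0) {
      # guarantee coverage: embed the seed match at a random offset
      at <- sample(0:72, 1)
      substr(win, at + 1, at + 7) <- seed_rc(mir, 2, 8)
    }
    hits <- scan_seed_sites(win, mir)
    n_hits <- n_hits + nrow(hits)
    if (nrow(hits) == 0) next
    for (r in seq_len(nrow(hits))) {
      cls <- hits$seed_class[r]
      has_a1 <- cls %in% c("8mer", "7mer-A1")
      m_hi <- if (cls %in% c("8mer", "7mer-m8")) 8 else 7
      matched <- substr(win, hits$start[r] + 1, hits$end[r] - has_a1)
      expect_equal(matched, seed_rc(mir, 2, m_hi), label = paste(cls, win))
      if (has_a1)
        expect_equal(substr(win, hits$end[r], hits$end[r]), "A")
    }
  }
  expect_gte(n_hits, 12L)
})
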