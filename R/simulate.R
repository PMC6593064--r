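# Seeded generators for synthetic study inputs. Defaults reproduce the
# structure of the motivating study: 66 cases vs 42 controls, a control
# risk-allele frequency of 0.357, a per-allele odds ratio of 1.8, an
# expression decrease per risk allele on the log10 scale, and a miRNA
# negatively correlated with its target (R^2 = 0.255 among carriers).

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a case-control genotype cohort
#'
#' Controls are drawn from Hardy-Weinberg proportions at the control
#' risk-allele frequency; cases from the same proportions reweighted by a
#' multiplicative per-allele odds ratio (`or^k` for `k` risk alleles,
#' renormalized) — the simplest sampling model consistent with reporting a
#' single allele odds ratio, under which the population allele odds ratio
#' equals `allele_or` exactly.
#'
#' @param n_cases,n_controls cohort sizes (defaults: the study's 66/42).
#' @param control_allele_freq risk-allele frequency in controls, in (0,1).
#' @param allele_or multiplicative per-allele odds ratio for case status.
#' @param ref_allele,risk_allele single-character allele labels.
#' @param snp_id column name for the genotype in the output.
#' @param seed integer seed (reproducible; `NULL` uses the current RNG
#'   state).
#' @return Data frame with columns `sample_id`, `group`, and `<snp_id>`
#'   (diploid genotype string); the risk allele is carried in
#'   `attr(, "risk_allele")`.
#' @examples
#' head(gen_genotypes(seed = 1))
#' @export
gen_genotypes <- function(n_cases = 66, n_controls = 42,
                          control_allele_freq = 0.357, allele_or = 1.8,
                          ref_allele = "C", risk_allele = "T",
                          snp_id = "rs4937333", seed = NULL) {
  p <- control_allele_freq
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("control_allele_freq must lie strictly inside (0, 1)",
         call. = FALSE)
  if (!is.finite(allele_or) || allele_or <= 0)
    stop("allele_or must be positive", call. = FALSE)
  q <- 1 - p
  hwe <- c(q^2, 2 * p * q, p^2)                 # 0, 1, 2 risk alleles
  case_p <- hwe * allele_or^(0:2)
  case_p <- case_p / sum(case_p)
  with_seed(seed, {
    g_ctl <- sample(0:2, n_controls, replace = TRUE, prob = hwe)
    g_cas <- sample(0:2, n_cases, replace = TRUE, prob = case_p)
    geno <- c(paste0(ref_allele, ref_allele),
              paste(sort(c(ref_allele, risk_allele)), collapse = ""),
              paste0(risk_allele, risk_allele))
    out <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n_cases + n_controls)),
      group = c(rep("case", n_cases), rep("control", n_controls)),
      stringsAsFactors = FALSE)
    out[[snp_id]] <- geno[c(g_cas, g_ctl) + 1L]
    attr(out, "risk_allele") <- risk_allele
    attr(out, "snp_id") <- snp_id
    out
  })
}

#' Simulate allele-dependent expression and a correlated miRNA
#'
#' For each genotyped sample, target-gene log10 expression is
#' `base_log10_mean + per_risk_allele_shift * k + N(0, noise_sd)` where `k`
#' counts risk alleles (a negative shift emulates reduced expression in
#' risk-allele carriers). miRNA log10 levels share a latent factor with the
#' target so that their squared correlation targets `mirna_target_r2`, with
#' a negative sign (high miRNA, low target). Ct pairs are back-computed so
#' that [relative_expression()] recovers the intended log10 values exactly.
#'
#' @param genotypes data frame from [gen_genotypes()] (or any data frame
#'   with `sample_id`, `group` and a genotype column named by its
#'   `snp_id` attribute).
#' @param base_log10_mean baseline log10 relative expression of the target.
#' @param per_risk_allele_shift additive shift per risk allele (log10
#'   scale).
#' @param noise_sd residual SD on the log10 scale, > 0.
#' @param mirna_target_r2 target squared correlation between miRNA and
#'   target log10 levels, in [0, 1).
#' @param cell_type label stored in the Ct records.
#' @param ct_reference_mean mean reference-gene Ct used when
#'   back-computing Ct pairs.
#' @param seed integer seed.
#' @return List with `ct` (long-format Ct table: `sample_id`, `group`,
#'   `cell_type`, `genotype`, `gene`, `ct_target`, `ct_reference`) and
#'   `expression` (per-sample `log10_target` and `log10_mirna`).
#' @export
gen_expression <- function(genotypes, base_log10_mean = 0,
                           per_risk_allele_shift = -0.3, noise_sd = 0.3,
                           mirna_target_r2 = 0.255, cell_type = "B",
                           ct_reference_mean = 20, seed = NULL) {
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be positive", call. = FALSE)
  if (mirna_target_r2 < 0 || mirna_target_r2 >= 1)
    stop("mirna_target_r2 must lie in [0, 1)", call. = FALSE)
  snp_id <- attr(genotypes, "snp_id")
  if (is.null(snp_id)) snp_id <- setdiff(names(genotypes),
                                         c("sample_id", "group"))[1]
  risk <- attr(genotypes, "risk_allele")
  if (is.null(risk)) risk <- "T"
  geno <- genotypes[[snp_id]]
  k <- vapply(strsplit(geno, ""), function(ch) sum(ch == risk), integer(1))
  n <- length(k)
  with_seed(seed, {
    log10_target <- base_log10_mean + per_risk_allele_shift * k +
      rnorm(n, 0, noise_sd)
    z <- as.numeric(scale(log10_target))
    rho <- sqrt(mirna_target_r2)
    log10_mirna <- -rho * z + sqrt(1 - mirna_target_r2) * rnorm(n)
    # invert 2^-dCt: dCt = -log2(rel_expr), ct_target = ct_reference + dCt
    ref_t <- ct_reference_mean + rnorm(n, 0, 0.5)
    ref_m <- ct_reference_mean + rnorm(n, 0, 0.5)
    ct <- rbind(
      data.frame(sample_id = genotypes$sample_id, group = genotypes$group,
                 cell_type = cell_type, genotype = geno, gene = "target",
                 ct_target = ref_t - log10_target / log10(2),
                 ct_reference = ref_t, stringsAsFactors = FALSE),
      data.frame(sample_id = genotypes$sample_id, group = genotypes$group,
                 cell_type = cell_type, genotype = geno, gene = "mirna",
                 ct_target = ref_m - log10_mirna / log10(2),
                 ct_reference = ref_m, stringsAsFactors = FALSE))
    list(ct = ct,
         expression = data.frame(sample_id = genotypes$sample_id,
                                 group = genotypes$group, genotype = geno,
                                 risk_alleles = k,
                                 log10_target = log10_target,
                                 log10_mirna = log10_mirna,
                                 stringsAsFactors = FALSE))
  })
}

#' Simulate a SNP-bearing UTR window with an allele-toggled seed site
#'
#' Generates a random miRNA and a random background window in which the
#' alternate allele completes a perfect 8mer seed site while the reference
#' allele carries a non-pairing mismatch at a chosen offset within the
#' seed match. Backgrounds are redrawn (within the seeded stream) until
#' the reference window has no canonical site overlapping the SNP, so the
#' two windows differ at exactly one position and only the alt allele is
#' bound.
#'
#' @param window_len window length in nt (default 60, the site-centered
#'   window used for the energy diagrams).
#' @param gc_background background GC content in (0,1).
#' @param mirna_len mature miRNA length, >= 18.
#' @param snp_offset_in_seed 0-based offset of the SNP within the 7-nt
#'   seed-match region (0 = the site position pairing miRNA base 8).
#' @param seed integer seed.
#' @return List with `window_ref`, `window_alt` (`nuc_sequence`), `snp`
#'   (a [snp_variant()]), `mirna`, and `site` (`c(start, end)`, 0-based
#'   half-open, of the embedded 8mer in the alt window).
#' @examples
#' w <- gen_snp_window(seed = 7)
#' scan_seed_sites(w$window_alt, w$mirna)
#' @export
gen_snp_window <- function(window_len = 60, gc_background = 0.5,
                           mirna_len = 22, snp_offset_in_seed = 3,
                           seed = NULL) {
  if (mirna_len < 18) stop("mirna_len must be >= 18", call. = FALSE)
  if (window_len < 12) stop("window too short to hold a site", call. = FALSE)
  o <- as.integer(snp_offset_in_seed)
  if (o < 0L || o > 6L)
    stop("snp_offset_in_seed must lie in 0..6", call. = FALSE)
  gc <- gc_background
  if (gc <= 0 || gc >= 1) stop("gc_background must be in (0,1)",
                               call. = FALSE)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  rand_seq <- function(n) paste(sample(names(probs), n, replace = TRUE,
                                       prob = probs), collapse = "")
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  wobble <- c(G = "U", U = "G")

  with_seed(seed, {
    mirna <- nuc_sequence(rand_seq(mirna_len), id = "mir_sim")
    m <- seq_chars(mirna)
    # alt-allele site, 5'->3' on the target: pairs m8..m2 then the A1 base
    site_seq <- c(rev(unname(comp[m[2:8]])), "A")
    site_start <- (window_len - 8L) %/% 2L             # 0-based
    snp_pos <- site_start + o
    alt_base <- site_seq[o + 1L]
    m_base <- m[8L - o]                                 # miRNA base opposite
    forbidden <- c(alt_base, unname(comp[m_base]))
    if (m_base %in% names(wobble))
      forbidden <- c(forbidden, unname(wobble[m_base]))
    ref_base <- setdiff(c("A", "C", "G", "U"), forbidden)[1]

    build <- function() {
      bg <- seq_chars(nuc_sequence(rand_seq(window_len)))
      bg[(site_start + 1L):(site_start + 8L)] <- site_seq
      alt <- paste(bg, collapse = "")
      bg[snp_pos + 1L] <- ref_base
      list(alt = alt, ref = paste(bg, collapse = ""))
    }
    for (try in 1:200) {
      w <- build()
      ref_sites <- scan_seed_sites(nuc_sequence(w$ref), mirna)
      ref_hit <- best_site_at(ref_sites, snp_pos)
      alt_sites <- scan_seed_sites(nuc_sequence(w$alt), mirna)
      alt_hit <- best_site_at(alt_sites, snp_pos)
      if (is.null(ref_hit) && !is.null(alt_hit) &&
          seed_class_rank(alt_hit$seed_class) >=
            seed_class_rank("7mer-m8")) {
        snp <- snp_variant("snp_sim", snp_pos, ref_base, alt_base,
                           window = nuc_sequence(w$ref))
        return(list(window_ref = nuc_sequence(w$ref, id = "window_ref"),
                    window_alt = nuc_sequence(w$alt, id = "window_alt"),
                    snp = snp, mirna = mirna,
                    site = c(site_start, site_start + 8L)))
      }
    }
    stop("failed to construct a clean SNP window in 200 attempts",
         call. = FALSE)
  })
}
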