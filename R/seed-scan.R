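#' Canonical miRNA seed-match scanning
#'
#' Locates canonical seed matches of a mature miRNA (guide strand, 5' to 3')
#' in a target UTR window and classifies each site by the TargetScan-style
#' hierarchy: `8mer` > `7mer-m8` > `7mer-A1` > `6mer`. A 6mer site is a
#' perfect Watson-Crick match of the target to the reverse complement of
#' miRNA positions 2-7; `m8` extends pairing to miRNA position 8, and `A1`
#' requires an adenosine in the target opposite miRNA position 1. G:U
#' wobble pairs are not counted as matches unless `allow_wobble = TRUE`.
#'
#' Reported intervals are 0-based, half-open, on the supplied window
#' (lengths 6-8; `A1` adenosines are included in the interval). Overlapping
#' matches anchored at the same seed core are deduplicated to the strongest
#' class.
#'
#' @param window target sequence window (`nuc_sequence` or character,
#'   DNA accepted), 5' to 3'.
#' @param mirna mature miRNA, 5' to 3', length >= 8.
#' @param allow_wobble count G:U pairs as seed matches.
#' @return A data frame with columns `mirna_id`, `start`, `end`,
#'   `seed_class` ordered by `start` (zero rows when no site is found).
#' @examples
#' mir <- "UGAGGUAGUAGGUUGUAUAGUU"       # let-7-like guide
#' win <- paste0("AAAAA", revcomp(substr(mir, 1, 8)), "AAAAA")
#' scan_seed_sites(win, mir)
#' @export
scan_seed_sites <- function(window, mirna, allow_wobble = FALSE) {
  window <- as_nuc(window); mirna <- as_nuc(mirna)
  if (nchar(mirna) < 8L)
    stop("miRNA must be at least 8 nt to define a seed", call. = FALSE)
  empty <- data.frame(mirna_id = character(0), start = integer(0),
                      end = integer(0), seed_class = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(window) < 6L) {
    warning("window shorter than 6 nt: no seed match possible")
    return(empty)
  }
  w <- seq_chars(window)
  m <- seq_chars(mirna)
  n <- length(w)

  matches <- function(target_base, mirna_base) {
    p <- paste0(target_base, mirna_base)
    ok <- c("AU", "UA", "CG", "GC")
    if (allow_wobble) ok <- c(ok, "GU", "UG")
    p %in% ok
  }
  # core match: target positions s..s+5 (1-based) pair miRNA 7..2
  core_at <- function(s) all(mapply(matches, w[s:(s + 5L)], m[7:2]))
  m8_at <- function(s) s >= 2L && matches(w[s - 1L], m[8])
  a1_at <- function(s) (s + 6L) <= n && w[s + 6L] == "A"

  out <- empty
  s <- 1L
  while (s + 5L <= n) {
    if (core_at(s)) {
      has_m8 <- m8_at(s)
      has_a1 <- a1_at(s)
      cls <- if (has_m8 && has_a1) "8mer"
             else if (has_m8) "7mer-m8"
             else if (has_a1) "7mer-A1"
             else "6mer"
      start0 <- (s - 1L) - if (has_m8) 1L else 0L
      end0 <- (s + 5L) + if (has_a1) 1L else 0L
      out <- rbind(out, data.frame(
        mirna_id = attr(mirna, "id"), start = start0, end = end0,
        seed_class = cls, stringsAsFactors = FALSE))
    }
    s <- s + 1L
  }
  out[order(out$start), , drop = FALSE]
}

seed_class_rank <- function(cls) {
  match(cls, c("none", "6mer", "7mer-A1", "7mer-m8", "8mer")) - 1L
}

# strongest site whose interval covers a 0-based position; NULL when none
best_site_at <- function(sites, pos0) {
  hit <- sites[sites$start <= pos0 & pos0 < sites$end, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  hit <- hit[order(-seed_class_rank(hit$seed_class), hit$start), , drop = FALSE]
  hit[1L, , drop = FALSE]
}

# strongest site overlapping a 0-based half-open interval; NULL when none
best_site_overlapping <- function(sites, start0, end0) {
  hit <- sites[sites$start < end0 & start0 < sites$end, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  hit <- hit[order(-seed_class_rank(hit$seed_class), hit$start), , drop = FALSE]
  hit[1L, , drop = FALSE]
}

#' Classify how a SNP changes a miRNA seed site
#'
#' Scans both allelic versions of a window and compares the strongest seed
#' class overlapping the SNP position. The effect label is one of
#' `site_created`, `site_destroyed`, `class_up`, `class_down`, `no_change`
#' (labels describe the alt allele relative to the ref allele).
#'
#' @param window window carrying the reference allele.
#' @param snp a [snp_variant()] consistent with the window.
#' @param mirna mature miRNA, 5' to 3'.
#' @param allow_wobble passed to [scan_seed_sites()].
#' @return List with `effect`, `snp_in_seed`, and per-allele site rows
#'   `ref_site` / `alt_site` (single-row data frames with `seed_class =
#'   "none"` when no site overlaps the SNP).
#' @export
classify_snp_effect <- function(window, snp, mirna, allow_wobble = FALSE) {
  window <- as_nuc(window)
  if (substr(unclass(window), snp$position + 1L, snp$position + 1L) !=
      snp$ref_allele)
    stop("window residue at SNP position does not match ref_allele",
         call. = FALSE)
  window_alt <- apply_alt_allele(window, snp)

  no_site <- data.frame(mirna_id = attr(as_nuc(mirna), "id"),
                        start = NA_integer_, end = NA_integer_,
                        seed_class = "none", stringsAsFactors = FALSE)
  ref_sites <- scan_seed_sites(window, mirna, allow_wobble = allow_wobble)
  alt_sites <- scan_seed_sites(window_alt, mirna,
                               allow_wobble = allow_wobble)
  ref_site <- best_site_at(ref_sites, snp$position)
  alt_site <- best_site_at(alt_sites, snp$position)
  # a SNP in a class extension (m8/A1) lies outside the weaker allele's
  # interval: recover that allele's site at the same locus by overlap
  if (is.null(ref_site) && !is.null(alt_site))
    ref_site <- best_site_overlapping(ref_sites, alt_site$start,
                                      alt_site$end)
  if (is.null(alt_site) && !is.null(ref_site))
    alt_site <- best_site_overlapping(alt_sites, ref_site$start,
                                      ref_site$end)
  if (is.null(ref_site)) ref_site <- no_site
  if (is.null(alt_site)) alt_site <- no_site
  r_ref <- seed_class_rank(ref_site$seed_class)
  r_alt <- seed_class_rank(alt_site$seed_class)
  effect <-
    if (r_ref == r_alt) "no_change"
    else if (r_ref == 0L) "site_created"
    else if (r_alt == 0L) "site_destroyed"
    else if (r_alt > r_ref) "class_up"
    else "class_down"
  list(effect = effect,
       snp_in_seed = r_ref > 0L || r_alt > 0L,
       ref_site = ref_site, alt_site = alt_site,
       snp_id = snp$snp_id)
}
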