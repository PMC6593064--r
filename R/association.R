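#' Case-control genotype count table for one biallelic SNP
#'
#' @param snp_id SNP identifier.
#' @param genotype_labels character vector of 3 diploid genotypes in the
#'   order homozygous-reference, heterozygous, homozygous-alternate
#'   (e.g. `c("CC", "CT", "TT")`).
#' @param case_counts,control_counts nonnegative integer counts per
#'   genotype, same order as `genotype_labels`.
#' @return An object of class `genotype_table`.
#' @examples
#' genotype_table("rs4937333", c("CC", "CT", "TT"), c(21, 24, 21),
#'                c(15, 24, 3))
#' @export
genotype_table <- function(snp_id, genotype_labels, case_counts,
                           control_counts) {
  if (length(genotype_labels) != 3L)
    stop("a biallelic SNP has exactly 3 genotype classes", call. = FALSE)
  case_counts <- as.integer(case_counts)
  control_counts <- as.integer(control_counts)
  if (length(case_counts) != 3L || length(control_counts) != 3L ||
      anyNA(case_counts) || anyNA(control_counts) ||
      any(case_counts < 0L) || any(control_counts < 0L))
    stop("counts must be 3 nonnegative integers per group", call. = FALSE)
  al <- unique(unlist(strsplit(genotype_labels, "")))
  if (length(al) != 2L)
    stop("genotype labels must involve exactly 2 alleles (biallelic SNP)",
         call. = FALSE)
  g1 <- strsplit(genotype_labels[1], "")[[1]]
  g2 <- strsplit(genotype_labels[2], "")[[1]]
  g3 <- strsplit(genotype_labels[3], "")[[1]]
  if (g1[1] != g1[2] || g3[1] != g3[2] || g2[1] == g2[2] || g1[1] == g3[1])
    stop("genotype labels must be hom-ref, het, hom-alt", call. = FALSE)
  structure(list(snp_id = as.character(snp_id),
                 genotype_labels = genotype_labels,
                 alleles = c(g1[1], g3[1]),
                 case_counts = case_counts,
                 control_counts = control_counts),
            class = "genotype_table")
}

#' 2x2 contingency table (exposure by case/control)
#'
#' Cell layout: `a` = exposed cases, `b` = exposed controls, `c` =
#' unexposed cases, `d` = unexposed controls, so the odds ratio is
#' `(a*d)/(b*c)`.
#'
#' @param a,b,c,d nonnegative integer cell counts; the total must be > 0.
#' @param exposure,reference optional labels for the two exposure levels.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d, exposure = "exposed",
                            reference = "unexposed") {
  cells <- as.integer(c(a, b, c, d))
  if (anyNA(cells) || any(cells < 0L))
    stop("cells must be nonnegative integers", call. = FALSE)
  if (sum(cells) == 0L) stop("empty table (N = 0)", call. = FALSE)
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
                 exposure = exposure, reference = reference),
            class = "contingency_2x2")
}

#' Allele counts from a genotype table
#'
#' Each allele is counted as twice its homozygote count plus the
#' heterozygote count, per group.
#'
#' @param table a [genotype_table()].
#' @return A 2x2 integer matrix: rows = the two alleles (reference allele
#'   first), columns = `case` / `control`.
#' @examples
#' tab <- genotype_table("rs4937333", c("CC", "CT", "TT"), c(21, 24, 21),
#'                       c(15, 24, 3))
#' alleles_from_genotypes(tab)   # cases C=66,T=66; controls C=54,T=30
#' @export
alleles_from_genotypes <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  ca <- table$case_counts; co <- table$control_counts
  m <- matrix(c(2L * ca[1] + ca[2], 2L * co[1] + co[2],
                2L * ca[3] + ca[2], 2L * co[3] + co[2]),
              nrow = 2, byrow = TRUE,
              dimnames = list(table$alleles, c("case", "control")))
  m
}

round_half_up <- function(x, digits = 3L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (a*d)/(b*c)`; the Woolf interval is
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. With a zero cell
#' the interval is undefined unless the Haldane-Anscombe correction
#' (+0.5 to every cell) is requested explicitly.
#'
#' @param t a [contingency_2x2()].
#' @param z normal quantile for the interval (default 1.959964, a 95% CI).
#' @param haldane apply the +0.5 continuity correction when a cell is 0.
#' @param comparison_label label carried into reports (e.g. `"TT vs CC"`).
#' @return List with `odds_ratio`, `ci_low`, `ci_high`, `defined` (FALSE
#'   when a zero cell leaves the interval undefined) and the label.
#' @examples
#' odds_ratio_ci(contingency_2x2(66, 30, 66, 54))   # OR 1.800 [1.026, 3.157]
#' @export
odds_ratio_ci <- function(t, z = 1.959964, haldane = FALSE,
                          comparison_label = "") {
  stopifnot(inherits(t, "contingency_2x2"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0L)) {
    if (!haldane)
      return(list(odds_ratio = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, defined = FALSE,
                  comparison_label = comparison_label))
    cells <- cells + 0.5
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(odds_ratio = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       defined = TRUE,
       comparison_label = comparison_label)
}

#' Pearson chi-square test for a 2x2 table
#'
#' The Pearson statistic `N*(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1
#' degree of freedom; with `continuity = TRUE`, `|ad-bc|` is replaced by
#' `max(0, |ad-bc| - N/2)` (Yates). A zero margin leaves the statistic
#' undefined and is signalled with `defined = FALSE`.
#'
#' @inheritParams odds_ratio_ci
#' @param continuity apply the Yates continuity correction.
#' @return List with `statistic`, `df`, `p` and `defined`.
#' @examples
#' chisq_test_2x2(contingency_2x2(66, 30, 66, 54))   # chi2 ~ 4.243
#' @export
chisq_test_2x2 <- function(t, continuity = FALSE) {
  stopifnot(inherits(t, "contingency_2x2"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0L)) {
    warning("zero margin: chi-square statistic undefined")
    return(list(statistic = NA_real_, df = 1L, p = NA_real_,
                defined = FALSE))
  }
  num <- abs(a * d - b * c)
  if (continuity) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(as.numeric(margins))
  list(statistic = stat, df = 1L,
       p = pchisq(stat, df = 1, lower.tail = FALSE), defined = TRUE)
}

#' Fisher exact test for a 2x2 table (two-sided)
#'
#' Conditional on both margins, the two-sided p-value is the sum of
#' hypergeometric point probabilities of all tables whose probability does
#' not exceed that of the observed table (within relative tolerance 1e-7).
#'
#' @inheritParams odds_ratio_ci
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(contingency_2x2(21, 3, 21, 15))
#' @export
fisher_exact_2x2 <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, m = r1, n = c + d, k = c1)
  p_obs <- dhyper(a, m = r1, n = c + d, k = c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Goodness of fit of observed genotype counts to the proportions
#' `p^2 : 2pq : q^2` implied by the sample allele frequency, on 1 degree
#' of freedom. Monomorphic samples are reported as inapplicable.
#'
#' @param genotypes integer vector of 3 genotype counts
#'   (hom-ref, het, hom-alt).
#' @param group_label label carried into reports (e.g. `"controls"`).
#' @return An object of class `hwe_result`: list with `chi2`, `df`, `p`,
#'   `applicable` and the label.
#' @examples
#' hwe_test(c(15, 24, 3), "controls")   # chi2 ~ 2.51
#' @export
hwe_test <- function(genotypes, group_label = "") {
  genotypes <- as.integer(genotypes)
  if (length(genotypes) != 3L || anyNA(genotypes) || any(genotypes < 0L))
    stop("'genotypes' must be 3 nonnegative counts", call. = FALSE)
  n <- sum(genotypes)
  if (n == 0L) stop("no individuals", call. = FALSE)
  p <- (2 * genotypes[1] + genotypes[2]) / (2 * n)
  if (p == 0 || p == 1)
    return(structure(list(chi2 = NA_real_, df = 1L, p = NA_real_,
                          applicable = FALSE, group_label = group_label),
                     class = "hwe_result"))
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((genotypes - expected)^2 / expected)
  structure(list(chi2 = chi2, df = 1L,
                 p = pchisq(chi2, df = 1, lower.tail = FALSE),
                 applicable = TRUE, group_label = group_label),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  if (x$applicable)
    cat(sprintf("HWE chi-square (%s): chi2 = %.3f, df = %d, p = %.4f\n",
                x$group_label, x$chi2, x$df, x$p))
  else
    cat(sprintf("HWE test (%s): inapplicable (monomorphic sample)\n",
                x$group_label))
  invisible(x)
}

# --- cohort-level association report -------------------------------------

normalize_genotype <- function(g) {
  # unordered diploid call: sort the two characters ("TC" -> "CT")
  g <- toupper(trimws(g))
  g[g == "" | g == "NA" | g == "./."] <- NA_character_
  vapply(g, function(x) {
    if (is.na(x)) return(NA_character_)
    ch <- strsplit(x, "")[[1]]
    if (length(ch) != 2L)
      stop("genotype must be two characters: '", x, "'", call. = FALSE)
    paste(sort(ch), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

aggregate_genotypes <- function(records, snp_id) {
  # records: data.frame with columns sample_id, group, and one column per SNP
  g <- normalize_genotype(records[[snp_id]])
  grp <- tolower(records$group)
  if (!all(grp %in% c("case", "control")))
    stop("group must be 'case' or 'control'", call. = FALSE)
  keep <- !is.na(g)
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(snp_id, ": ", dropped,
            " sample(s) with missing calls excluded (pairwise deletion)")
  g <- g[keep]; grp <- grp[keep]
  alleles <- sort(unique(unlist(strsplit(g, ""))))
  if (length(alleles) > 2L) {
    freq <- sort(table(unlist(strsplit(g, ""))), decreasing = TRUE)
    rare <- setdiff(alleles, names(freq)[1:2])
    bad <- records$sample_id[keep][grepl(paste(rare, collapse = "|"), g)]
    stop(snp_id, ": more than two alleles observed (",
         paste(alleles, collapse = "/"), "); offending samples: ",
         paste(head(unique(bad), 10), collapse = ", "), call. = FALSE)
  }
  list(genotype = g, group = grp, alleles = alleles, n_dropped = dropped)
}

snp_counts_to_table <- function(snp_id, genotype, case_n, control_n) {
  # order genotypes as hom-major(control), het, hom-minor and build the table
  genotype <- normalize_genotype(genotype)
  alleles <- sort(unique(unlist(strsplit(genotype, ""))))
  if (length(alleles) == 1L) {
    return(list(monomorphic = TRUE, snp_id = snp_id,
                genotype = genotype, case_n = case_n, control_n = control_n))
  }
  ctl_allele <- setNames(numeric(2), alleles)
  for (i in seq_along(genotype)) {
    ch <- strsplit(genotype[i], "")[[1]]
    for (b in ch) ctl_allele[b] <- ctl_allele[b] + control_n[i]
  }
  major <- names(which.max(ctl_allele))     # first alphabetically on ties
  minor <- setdiff(alleles, major)
  # display order: hom-major, het (major allele written first), hom-minor
  labels <- c(paste0(major, major), paste0(major, minor),
              paste0(minor, minor))
  idx <- match(normalize_genotype(labels), genotype)
  caseN <- ifelse(is.na(idx), 0L, case_n[idx])
  ctlN <- ifelse(is.na(idx), 0L, control_n[idx])
  list(monomorphic = FALSE,
       table = genotype_table(snp_id, labels, caseN, ctlN),
       major = major, minor = minor)
}

analyze_snp <- function(prep, haldane = FALSE) {
  # full association workup for one polymorphic SNP
  tab <- prep$table
  ca <- tab$case_counts; co <- tab$control_counts
  lab <- tab$genotype_labels
  one <- function(t2, label) {
    res <- odds_ratio_ci(t2, haldane = haldane, comparison_label = label)
    res$p_chisq <- chisq_test_2x2(t2)$p
    res$p_fisher <- fisher_exact_2x2(t2)
    res
  }
  het <- one(contingency_2x2(ca[2], co[2], ca[1], co[1]),
             paste(lab[2], "vs", lab[1]))
  hom <- one(contingency_2x2(ca[3], co[3], ca[1], co[1]),
             paste(lab[3], "vs", lab[1]))
  am <- alleles_from_genotypes(tab)
  allele <- one(contingency_2x2(am[2, "case"], am[2, "control"],
                                am[1, "case"], am[1, "control"]),
                paste(prep$minor, "vs", prep$major))
  list(snp_id = tab$snp_id, table = tab,
       hwe = list(case = hwe_test(ca, "cases"),
                  control = hwe_test(co, "controls")),
       genotype_or = list(het = het, hom = hom),
       allele_or = allele, allele_counts = am)
}

#' Full genotype/allele association report
#'
#' Builds the complete association report for a cohort: per SNP,
#' Hardy-Weinberg tests in each group, genotype odds ratios against the
#' homozygote of the control-major allele, the allele odds ratio, Woolf
#' 95% confidence intervals, and both Pearson chi-square and Fisher exact
#' p-values side by side. Monomorphic SNPs are reported with dashes.
#'
#' @param records per-sample data frame with columns `sample_id`, `group`
#'   (`case`/`control`) and one column per SNP holding unordered diploid
#'   genotypes (e.g. `"CT"`). Missing calls are excluded per SNP with a
#'   message.
#' @param counts alternative pre-aggregated input: data frame with columns
#'   `snp_id`, `genotype`, `case_n`, `control_n` (one row per observed
#'   genotype). Exactly one of `records`/`counts` must be given.
#' @param haldane passed to [odds_ratio_ci()] for zero cells.
#' @return An object of class `association_report`: list of per-SNP results
#'   plus a formatted data frame (`$formatted`) mirroring the layout of a
#'   published genotype/allele association table.
#' @examples
#' counts <- read.delim(system.file("extdata", "table1_counts.tsv",
#'                                  package = "seedshift"),
#'                      comment.char = "#")
#' rep <- build_table1(counts = counts)
#' rep$formatted
#' @export
build_table1 <- function(records = NULL, counts = NULL, haldane = FALSE) {
  if (is.null(records) == is.null(counts))
    stop("give exactly one of 'records' or 'counts'", call. = FALSE)
  if (!is.null(records)) {
    if (nrow(records) == 0L)
      return(structure(list(snps = list(),
                            formatted = data.frame()),
                       class = "association_report"))
    snp_cols <- setdiff(names(records), c("sample_id", "group"))
    counts <- do.call(rbind, lapply(snp_cols, function(sid) {
      agg <- aggregate_genotypes(records, sid)
      tb <- table(factor(agg$group, levels = c("case", "control")),
                  agg$genotype)
      data.frame(snp_id = sid, genotype = colnames(tb),
                 case_n = as.integer(tb["case", ]),
                 control_n = as.integer(tb["control", ]),
                 stringsAsFactors = FALSE)
    }))
  }
  counts$genotype <- normalize_genotype(counts$genotype)
  snps <- unique(counts$snp_id)
  results <- lapply(snps, function(sid) {
    sub <- counts[counts$snp_id == sid, ]
    prep <- snp_counts_to_table(sid, sub$genotype, sub$case_n, sub$control_n)
    if (prep$monomorphic) prep else analyze_snp(prep, haldane = haldane)
  })
  names(results) <- snps
  structure(list(snps = results,
                 formatted = format_association_report(results)),
            class = "association_report")
}

format_association_report <- function(results) {
  fmt3 <- function(x) sprintf("%.3f", round_half_up(x, 3))
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (res in results) {
    if (isTRUE(res$monomorphic)) {
      n_ca <- sum(res$case_n); n_co <- sum(res$control_n)
      add(snp_id = res$snp_id, level = res$genotype[1],
          case = sprintf("%d (100)", n_ca),
          control = sprintf("%d (100)", n_co),
          odds_ratio = "-", ci95 = "-", p_chisq = "-", p_fisher = "-")
      next
    }
    tab <- res$table
    n_ca <- sum(tab$case_counts); n_co <- sum(tab$control_counts)
    pct <- function(x, n) sprintf("%d (%.1f)", x, 100 * x / n)
    orfmt <- function(r) {
      if (!r$defined) return(c("-", "-"))
      c(fmt3(r$odds_ratio),
        paste0(fmt3(r$ci_low), "-", fmt3(r$ci_high)))
    }
    gen_rows <- list(NULL, res$genotype_or$het, res$genotype_or$hom)
    for (k in 1:3) {
      r <- gen_rows[[k]]
      ors <- if (is.null(r)) c("", "") else orfmt(r)
      add(snp_id = res$snp_id, level = tab$genotype_labels[k],
          case = pct(tab$case_counts[k], n_ca),
          control = pct(tab$control_counts[k], n_co),
          odds_ratio = ors[1], ci95 = ors[2],
          p_chisq = if (is.null(r)) "" else fmt3(r$p_chisq),
          p_fisher = if (is.null(r)) "" else fmt3(r$p_fisher))
    }
    am <- res$allele_counts
    a_tot_ca <- sum(am[, "case"]); a_tot_co <- sum(am[, "control"])
    for (k in 1:2) {
      r <- if (k == 2) res$allele_or else NULL
      ors <- if (is.null(r)) c("", "") else orfmt(r)
      add(snp_id = res$snp_id, level = rownames(am)[k],
          case = pct(am[k, "case"], a_tot_ca),
          control = pct(am[k, "control"], a_tot_co),
          odds_ratio = ors[1], ci95 = ors[2],
          p_chisq = if (is.null(r)) "" else fmt3(r$p_chisq),
          p_fisher = if (is.null(r)) "" else fmt3(r$p_fisher))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.association_report <- function(x, ...) {
  print(x$formatted, row.names = FALSE)
  invisible(x)
}
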