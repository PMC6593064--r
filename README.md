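# seedshift

Allele-specific miRNA target-site analysis for 3′-UTR SNPs.

A single-nucleotide polymorphism inside a microRNA binding site can change
how strongly the miRNA represses its host gene — a common mechanism behind
regulatory disease associations. `seedshift` implements the full desk
analysis for such a locus as a tested, reusable R pipeline:

1. **Case–control association** — Hardy–Weinberg χ² tests, genotype and
   allele contingency tables, odds ratios with Woolf 95% confidence
   intervals, and both Pearson χ² and Fisher exact p-values reported side
   by side.
2. **Seed-site scanning** — canonical TargetScan-style seed classes
   (`8mer > 7mer-m8 > 7mer-A1 > 6mer`, strict Watson–Crick by default)
   located in UTR windows, with per-allele classification of how a SNP
   creates, destroys, or re-grades a site.
3. **Three-state binding thermodynamics** — for each allele, a
   nearest-neighbor energy diagram: E_target (MFE fold of the window),
   E_intermediate (constrained fold with the site forced open), and
   E_complex = E_intermediate + E_duplex (miRNA:site hybridization), with
   ΔE_a = E_intermediate − E_target (activation/opening cost) and
   ΔE_b = E_complex − E_target (binding energy; more negative = stronger).
   Folding is Zuker-style dynamic programming over non-crossing structures;
   the duplex is an RNAduplex-style intermolecular DP. The identity
   ΔE_b = ΔE_a + E_duplex holds exactly by construction.
4. **qPCR expression analysis** — 2^−ΔCt relative expression with log10
   transform, genotype/group contrasts (Welch t, one-way ANOVA), and the
   miRNA-versus-target linear regression.
5. **Synthetic data** — seeded generators for genotype cohorts under a
   multiplicative per-allele risk model, allele-shifted expression with a
   negatively correlated miRNA, and SNP windows whose seed site is toggled
   by the allele, so every stage runs and is testable without downloads.

The statistical model in brief: for a biallelic SNP with allele counts
arranged as a 2×2 exposure-by-outcome table, OR = ad/bc with the Woolf
interval exp(ln OR ± z·√(1/a+1/b+1/c+1/d)); Hardy–Weinberg fit is tested by
χ² against (p², 2pq, q²); the Fisher p-value sums hypergeometric point
probabilities ≤ that of the observed table. Folding free energies are
nearest-neighbor sums (Turner-2004-style stacks with G:U wobble, tabulated
loop penalties with logarithmic extrapolation, affine multibranch penalty,
4.09 kcal/mol duplex initiation, 0.5 kcal/mol AU/GU end penalty) at 37 °C.

## Worked example

Reproduce the association table for the study cohort (66 SLE cases, 42
controls) from the bundled genotype counts:

```r
library(seedshift)
counts <- read.delim(system.file("extdata", "table1_counts.tsv",
                                 package = "seedshift"), comment.char = "#")
rep <- build_table1(counts = counts)
rep$formatted[rep$formatted$snp_id == "rs4937333", ]
#>     snp_id level      case   control odds_ratio         ci95 p_chisq p_fisher
#>  rs4937333    CC 21 (31.8) 15 (35.7)
#>  rs4937333    CT 24 (36.4) 24 (57.1)      0.714  0.299-1.707   0.449    0.511
#>  rs4937333    TT 21 (31.8)   3 (7.1)      5.000 1.259-19.860   0.016    0.021
#>  rs4937333     C 66 (50.0) 54 (64.3)
#>  rs4937333     T 66 (50.0) 30 (35.7)      1.800  1.026-3.157   0.039    0.049

rep$snps$rs4937333$hwe$control
#> HWE chi-square (controls): chi2 = 2.510, df = 1, p = 0.1132
```

The T allele is enriched in cases (OR 1.800, 95% CI 1.026–3.157) and the
TT genotype carries a five-fold odds ratio versus CC; the control genotype
distribution is consistent with Hardy–Weinberg equilibrium.

Thermodynamics on a synthetic SNP window whose alternate allele completes
an 8mer seed site:

```r
w <- gen_snp_window(seed = 7)
compare_alleles(w$window_ref, w$snp, w$mirna)
#> <allele_comparison> snp_sim (site_created)
#>   ref: site none     dE_a   0.00  dE_b   0.00
#>   alt: site 8mer     dE_a   2.44  dE_b  -9.45
#>   delta_binding -9.45 kcal/mol; favored allele: alt
```

Opening the site in the alt window costs 2.44 kcal/mol (ΔE_a), but duplex
formation more than repays it (ΔE_b = −9.45 kcal/mol), so the miRNA favors
the alt allele; the ref allele has no site and does not bind.

An end-to-end run (simulation → association → scan → thermodynamics →
expression) with a combined JSON/Markdown report:

```r
run_pipeline(list(out_dir = "out", seed = 1))
```

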