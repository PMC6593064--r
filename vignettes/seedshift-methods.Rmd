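---
title: "Methods: allele-specific miRNA target-site analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific miRNA target-site analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedshift)
```

# Scope

`seedshift` asks a single, concrete question about a biallelic SNP in a
3′-UTR: does the variant change miRNA-mediated repression of the host
gene? It answers it with four coupled analyses — case–control association,
seed-site scanning, three-state binding thermodynamics, and qPCR
expression statistics — plus generators that produce synthetic inputs with
the same statistical structure, so the whole pipeline is exercisable and
testable offline.

# Association statistics

Genotype counts for cases and controls are the primary input; allele
counts derive as twice the homozygote count plus the heterozygote count.

* **Odds ratios** use the cross-product ratio on a 2×2 table with the
  **Woolf** log-scale interval, `exp(ln OR ± z·SE)`,
  `SE = sqrt(1/a + 1/b + 1/c + 1/d)`, `z = 1.959964`. Reported tables
  round half-up to 3 decimals. Genotype odds ratios are taken against the
  homozygote of the control-major allele, which leaves the reference rows
  blank in the formatted table; the heterozygote label is written with the
  major allele first (e.g. `GA` when G is major).
* **Zero cells** leave the interval undefined by default; the
  Haldane–Anscombe +0.5 correction is applied only on explicit request.
  A silent correction would mask sparse-data problems in small cohorts.
* **Both p-values are always reported.** Published association tables are
  frequently ambiguous about whether an allele-test p came from a Pearson
  χ² or a Fisher exact test — the two disagree noticeably at double-digit
  cell counts. Rather than guess which one a given table printed,
  `build_table1()` computes the uncorrected Pearson χ²
  (`N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))`, df = 1; Yates-corrected variant by
  flag) *and* the two-sided Fisher exact p (sum of hypergeometric point
  probabilities not exceeding the observed table's, with a 1e-7 relative
  tolerance guard against floating-point ties) side by side.
* **Hardy–Weinberg equilibrium** is a χ² goodness-of-fit of observed
  genotype counts to `(p², 2pq, q²)` on 1 df. Monomorphic samples are
  flagged inapplicable rather than reported as 0/0. HWE adherence is
  asserted in **controls**: cases are ascertained on disease status, so a
  true risk variant is *expected* to distort case genotype frequencies
  (under a multiplicative risk model the case population is not in HWE),
  and quality control by HWE is standard practice in the control group
  only. Both groups' tests are nevertheless computed and reported.

Missing genotype calls are excluded per SNP (pairwise deletion) with a
logged count; more than two observed alleles is a validation error that
names the offending samples.

# Seed-site model

Sites follow the canonical seed hierarchy: a 6mer is an exact
Watson–Crick match of the target to the reverse complement of miRNA
positions 2–7; m8 pairing extends it to `7mer-m8`, an adenosine opposite
position 1 gives `7mer-A1`, and both give `8mer`. G:U wobble is **not** a
match by default (`allow_wobble` relaxes this): wobble-containing seeds
are weakly repressive and counting them would inflate site calls.
Coordinates are 0-based half-open on the supplied window; an optional
genomic offset is carried for reporting only.

When alleles are compared, each allele's strongest site overlapping the
SNP is used. A subtlety: a SNP that sits in a class *extension* (the m8 or
A1 position) lies outside the weaker allele's reported interval. The
classifier therefore falls back to the strongest site overlapping the
*other* allele's interval, so a 6mer→7mer-m8 upgrade is labelled
`class_up` rather than `site_created`.

# Thermodynamic model

Binding is modelled as a three-state diagram per allele:

* `E_target` — minimum free energy of the window (Zuker dynamic
  programming over non-crossing structures: hairpins, stacks,
  bulge/internal loops to a size cap, multibranch loops with an affine
  penalty; the open chain scores 0, so the MFE is never positive).
* `E_intermediate` — the same minimization with every site position
  forbidden from pairing (hard constraint). This is the accessible
  "transition state"; by construction `E_intermediate ≥ E_target`.
* `E_complex = E_intermediate + E_duplex`, where `E_duplex` is the
  minimum hybridization energy of the miRNA with the extracted site
  sequence over chains of intermolecular pairs interrupted by bulge or
  interior loops capped at 4 unpaired bases per side, plus a duplex
  initiation constant. A duplex that cannot reach a negative total is
  reported as non-binding with energy 0.

The derived quantities are `ΔE_a = E_intermediate − E_target` (cost of
opening the site) and `ΔE_b = E_complex − E_target` (net binding energy).
The two-step accessibility decomposition makes `ΔE_b = ΔE_a + E_duplex`
an exact identity, which the tests assert to machine precision. An allele
with no site does not bind: its diagram is degenerate with `ΔE_b = 0`.

## Energy parameters

The bundled tables are Turner-2004-style: the 21 unique Watson–Crick and
G:U stack free energies (37 °C, kcal/mol) expanded to all 36 oriented pair
combinations under the strand-flip symmetry, which the loader validates;
hairpin (≥3 nt), bulge, and internal loop initiation penalties tabulated
to size 30 and extrapolated as `ΔG(s₀) + 1.75·RT·ln(s/s₀)` beyond;
multibranch affine penalty `a = 3.4`, `b = 0.4` per branch, `c = 0`
per unpaired base; duplex initiation 4.09 kcal/mol; and a 0.5 kcal/mol
terminal penalty per AU or G:U pair side facing a loop or the exterior
(helix-internal stacks exempt; bulges are treated as interrupting
stacking). Both tables ship as documented TSVs
(`inst/extdata/nn_stacks.tsv`, `loop_penalties.tsv`) so users can swap
parameter sets. Temperature is fixed at 37 °C.

Because published figures of this kind are produced with ViennaRNA's full
parameter set (coaxial stacking, tabulated mismatches, dangles) on the
authors' exact genomic window, *absolute* energies from this model will
not equal RNAfold/RNAcofold outputs. All of the package's claims are
therefore comparative and oracle-based: the dynamic program is checked
exactly against exhaustive enumeration of all legal structures on short
sequences, and allele comparisons are validated on constructed windows
where the direction of the effect is known. The default analysis window
is 60 nt centered on the SNP, with off-center placement available.

## Numerical choices

Energies are doubles summed from 2-decimal table entries; oracle
comparisons use a 1e-9 tolerance. Traceback explores cases in a fixed
order that prefers leaving a base unpaired, so reported structures are
deterministic and biased toward fewer pairs on ties; the full
"fewest pairs, then lexicographic" tie-break is approximated locally
rather than enforced globally (a global enforcement would require a
second DP pass and changes no energy). Degenerate inputs are defined
explicitly: zero-length site intervals give `ΔE_a = ΔE_b = 0`; windows
shorter than 6 nt scan to an empty site list with a warning; constraint
intervals out of bounds are errors.

# Expression analysis

Relative expression is `2^−ΔCt` with `ΔCt = Ct_target − Ct_reference`
computed per sample against its own reference gene (no ΔΔCt calibrator is
assumed — when only a reference-gene normalization and a log transform
are specified, introducing a calibrator sample would be an invention).
All statistics run on the log10 scale. Two-group contrasts default to the
**Welch** t-test: when a design says only "t-test", the unequal-variance
form is the robustness-preserving reading, and a pooled-variance flag is
provided. Three genotype groups use a classic one-way ANOVA F-test. The
miRNA–target relationship is ordinary least squares with `R²` equal to
the squared Pearson correlation and a two-sided slope t-test. Ct values
are validated into `(0, 45]`.

# Synthetic-data generators

The generators encode the study conditions as defaults, chosen once:
66 cases / 42 controls, control risk-allele frequency 0.357, per-allele
odds ratio 1.8, expression shift −0.3 log10 units per risk allele with
residual SD 0.3 (a visible but noisy effect, matching the reported
figure-level separation), miRNA–target `R² = 0.255`, 60-nt windows at
GC 0.5 with a 22-nt miRNA and the SNP at offset 3 of the seed match.

* **Genotypes**: controls are multinomial draws from HWE proportions;
  cases reweight those proportions by `OR^k` for `k` risk alleles. Under
  this multiplicative model the population allele odds ratio equals the
  nominal OR exactly, so estimator checks have a sharp target.
* **Expression**: target log10 values are linear in the risk-allele count
  plus Gaussian noise; miRNA values are built from the standardized
  target values as `−√R²·z + √(1−R²)·ε`, giving a negative correlation
  with the intended squared magnitude. Ct pairs are back-computed so the
  2^−ΔCt transform recovers the intended values exactly (the round trip
  is asserted at 1e-9).
* **Windows**: a perfect 8mer site for a random miRNA is embedded in a
  random background; the reference allele replaces one seed-match base
  with a residue that can neither Watson–Crick nor wobble pair with the
  opposing miRNA base. Backgrounds are redrawn (within the seeded stream)
  until the reference window has no canonical site overlapping the SNP.

What the generators deliberately do **not** emulate: linkage between
SNPs, genotyping error, qPCR efficiency differences or plate effects,
cell-type-specific reference genes, sequence conservation, or any
read-level data. Passing tests on synthetic data therefore demonstrate
that the estimators and the thermodynamic ranking behave correctly under
the assumed sampling models — not that those models capture every feature
of a real cohort.

# Orchestration

`run_pipeline()` executes the enabled stages in order from a YAML or list
configuration with a single seed, writing per-stage tables, a
schema-validated `report.json`, and a human-readable `report.md`; reports
carry no timestamps, so equal seeds give byte-identical output. A failing
stage preserves completed outputs and a manifest. The package's interface
is its functions; the pipeline entry point is a thin layer over them and
is equally usable from `Rscript -e`.

# Problem sizes used in the checks

The bundled checks run at sizes chosen to make their statistical
assertions sharp while staying quick on a laptop: exhaustive-enumeration
agreement on 200 random sequences up to 20 nt; site-opening monotonicity
on 500 random 60-nt windows; allele-direction checks on 100 synthetic SNP
windows; 2000 replicates for CI coverage (at the study's 66/42 sizes) and
for χ² type-I error (200 per group); 500 replicates for `R²` recovery at
n = 66; and a 5000/5000 cohort for odds-ratio consistency.

# Known limitations

* Folding has no partition function: site accessibility is a single
  constrained MFE, not an ensemble opening probability.
* No 3′-supplementary pairing, conservation, or context scoring — the
  seed scan is a match classifier, not a repression predictor.
* The duplex model omits dangles and coaxial stacking, and interior
  loops in both DPs use size-only penalties (no mismatch tables).
* Association analysis is single-SNP: no covariates, stratification
  control, haplotypes, or multiple-testing correction.
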