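#' Three-state binding energy diagram for a miRNA site
#'
#' Computes the three-state diagram for miRNA binding to a structured
#' target window: `E_target`, the minimum free energy of the window;
#' `E_intermediate`, the constrained minimum with the binding site forced
#' unpaired (the transition state in which the site is accessible); and
#' `E_complex = E_intermediate + E_duplex`, the bound state, where
#' `E_duplex` is the miRNA:site hybridization energy. The derived
#' quantities are the activation energy `dE_a = E_intermediate - E_target`
#' (cost of opening the site, always >= 0) and the binding energy
#' `dE_b = E_complex - E_target` (net gain of binding; more negative means
#' stronger binding). By construction `dE_b = dE_a + E_duplex` exactly.
#'
#' @param window target window (`nuc_sequence` or character), 5' to 3'.
#' @param site integer `c(start, end)`: 0-based half-open interval of the
#'   binding site within the window. A zero-length interval yields the
#'   degenerate diagram `dE_a = dE_b = 0`.
#' @param mirna mature miRNA, 5' to 3'.
#' @param model an [energy_model()].
#' @return An object of class `energy_diagram`: list with `E_target`,
#'   `E_intermediate`, `E_complex`, `dE_a`, `dE_b`, `E_duplex`, `site`,
#'   and the two folded structures.
#' @examples
#' mir <- nuc_sequence("UCACAGUGGCUAAGUUCUGC", id = "mir")
#' win <- paste0(strrep("A", 26), revcomp(substr(mir, 2, 8)), "A",
#'               strrep("A", 26))
#' energy_diagram(win, c(26, 34), mir)
#' @export
energy_diagram <- function(window, site, mirna,
                           model = default_energy_model()) {
  window <- as_nuc(window)
  if (length(site) != 2L || anyNA(site))
    stop("'site' must be c(start, end), 0-based half-open", call. = FALSE)
  site <- as.integer(site)
  n <- nchar(window)
  if (site[1] > site[2] || site[1] < 0L || site[2] > n)
    stop("site interval outside the window", call. = FALSE)

  target <- mfe_fold(window, model)
  if (site[2] == site[1]) {
    # degenerate: nothing to open, nothing to bind
    out <- list(E_target = target$energy, E_intermediate = target$energy,
                E_complex = target$energy, dE_a = 0, dE_b = 0,
                E_duplex = 0, site = site,
                target_structure = target, intermediate_structure = target,
                duplex = list(energy = 0,
                              pairs = data.frame(mirna_pos = integer(0),
                                                 site_pos = integer(0))))
    return(structure(out, class = "energy_diagram"))
  }
  intermediate <- constrained_mfe(window, site, model)
  site_seq <- substr(unclass(window), site[1] + 1L, site[2])
  dup <- duplex_energy(mirna, nuc_sequence(site_seq, id = "site"), model)
  E_t <- target$energy
  E_i <- intermediate$energy
  E_c <- E_i + dup$energy
  structure(list(E_target = E_t, E_intermediate = E_i, E_complex = E_c,
                 dE_a = E_i - E_t, dE_b = E_c - E_t, E_duplex = dup$energy,
                 site = site, target_structure = target,
                 intermediate_structure = intermediate, duplex = dup),
            class = "energy_diagram")
}

#' @export
print.energy_diagram <- function(x, ...) {
  cat("<energy_diagram> (kcal/mol)\n")
  cat(sprintf("  E_target       %7.2f\n", x$E_target))
  cat(sprintf("  E_intermediate %7.2f   (dE_a = %.2f)\n",
              x$E_intermediate, x$dE_a))
  cat(sprintf("  E_complex      %7.2f   (dE_b = %.2f)\n",
              x$E_complex, x$dE_b))
  invisible(x)
}

#' Compare miRNA binding energetics between two alleles of a SNP
#'
#' Runs the seed scan on the reference and alternate allelic windows,
#' builds each allele's three-state diagram on its own strongest seed site
#' overlapping the SNP, and compares binding energies. An allele without a
#' site overlapping the SNP does not bind: its diagram is degenerate with
#' `dE_b = 0`. The favored allele is the one with the lower (more
#' negative) binding energy; `delta_binding = dE_b(alt) - dE_b(ref)`.
#'
#' @param window_ref window carrying the reference allele, 5' to 3'.
#' @param snp a [snp_variant()] consistent with `window_ref`.
#' @param mirna mature miRNA, 5' to 3'.
#' @param model an [energy_model()].
#' @param allow_wobble passed to [scan_seed_sites()].
#' @return An object of class `allele_comparison`: list with `snp_id`,
#'   per-allele diagrams `ref` / `alt`, the seed-scan effect label,
#'   `delta_binding`, `favored_allele` (`"ref"`, `"alt"` or `"tie"`), and
#'   `informative` (FALSE when neither allele has a site).
#' @export
compare_alleles <- function(window_ref, snp, mirna,
                            model = default_energy_model(),
                            allow_wobble = FALSE) {
  window_ref <- as_nuc(window_ref)
  window_alt <- apply_alt_allele(window_ref, snp)
  cls <- classify_snp_effect(window_ref, snp, mirna,
                             allow_wobble = allow_wobble)

  diagram_for <- function(win, site_row) {
    if (site_row$seed_class == "none")
      energy_diagram(win, c(0L, 0L), mirna, model)
    else
      energy_diagram(win, c(site_row$start, site_row$end), mirna, model)
  }
  ref_d <- diagram_for(window_ref, cls$ref_site)
  alt_d <- diagram_for(window_alt, cls$alt_site)

  delta <- alt_d$dE_b - ref_d$dE_b
  favored <- if (delta < 0) "alt" else if (delta > 0) "ref" else "tie"
  structure(list(snp_id = snp$snp_id, ref = ref_d, alt = alt_d,
                 ref_site = cls$ref_site, alt_site = cls$alt_site,
                 effect = cls$effect, delta_binding = delta,
                 favored_allele = favored,
                 informative = cls$ref_site$seed_class != "none" ||
                   cls$alt_site$seed_class != "none"),
            class = "allele_comparison")
}

#' @export
print.allele_comparison <- function(x, ...) {
  cat(sprintf("<allele_comparison> %s (%s)\n", x$snp_id, x$effect))
  cat(sprintf("  ref: site %-8s dE_a %6.2f  dE_b %6.2f\n",
              x$ref_site$seed_class, x$ref$dE_a, x$ref$dE_b))
  cat(sprintf("  alt: site %-8s dE_a %6.2f  dE_b %6.2f\n",
              x$alt_site$seed_class, x$alt$dE_a, x$alt$dE_b))
  cat(sprintf("  delta_binding %.2f kcal/mol; favored allele: %s\n",
              x$delta_binding, x$favored_allele))
  invisible(x)
}
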