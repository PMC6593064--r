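#' Minimum free energy secondary structure
#'
#' Folds an RNA sequence under the nearest-neighbor model by Zuker-style
#' dynamic programming over non-crossing structures (hairpin, stack,
#' bulge/internal loops up to the model's size cap, and multibranch loops
#' with an affine penalty). The open chain has energy 0, so the reported
#' minimum free energy is never positive.
#'
#' @param seq a `nuc_sequence` or character scalar (DNA accepted).
#' @param model an [energy_model()]; defaults to the bundled parameters.
#' @return An object of class `rna_structure`: list with `seq`,
#'   `dotbracket`, `energy` (kcal/mol) and `pairs` (1-based partner index,
#'   `NA` when unpaired).
#' @examples
#' mfe_fold("GGGGAAAACCCC")
#' @seealso [constrained_mfe()], [duplex_energy()], [structure_energy()]
#' @export
mfe_fold <- function(seq, model = default_energy_model()) {
  seq <- as_nuc(seq)
  enc <- encode_seq(seq)
  res <- c_mfe_fold(enc, logical(length(enc)), unclass(model))
  new_rna_structure(seq, res$pairs, res$energy)
}

#' Constrained minimum free energy with a site held open
#'
#' Folds as [mfe_fold()] but forbids every position of a given interval
#' from pairing — the "transition state" fold in which the miRNA binding
#' site is accessible. With an empty interval the result equals the
#' unconstrained fold.
#'
#' @inheritParams mfe_fold
#' @param unpaired integer vector `c(start, end)`: 0-based, half-open
#'   interval of positions forced to stay unpaired.
#' @return An `rna_structure` (see [mfe_fold()]).
#' @examples
#' constrained_mfe("GGGGAAAACCCC", c(0, 4))
#' @export
constrained_mfe <- function(seq, unpaired, model = default_energy_model()) {
  seq <- as_nuc(seq)
  n <- nchar(seq)
  if (length(unpaired) != 2L || anyNA(unpaired))
    stop("'unpaired' must be c(start, end), 0-based half-open", call. = FALSE)
  a <- as.integer(unpaired[1]); b <- as.integer(unpaired[2])
  if (a > b || a < 0L || b > n)
    stop("constraint interval out of bounds", call. = FALSE)
  mask <- logical(n)
  if (b > a) mask[(a + 1L):b] <- TRUE
  enc <- encode_seq(seq)
  res <- c_mfe_fold(enc, mask, unclass(model))
  out <- new_rna_structure(seq, res$pairs, res$energy)
  out$constraint <- c(a, b)
  out
}

#' miRNA:target duplex hybridization energy
#'
#' Minimum hybridization energy over intermolecular alignments in which a
#' chain of base pairs (antiparallel) is interrupted only by bulge or
#' internal loops with at most `loop_cap` unpaired bases per side
#' (RNAduplex-style dynamic programming). The duplex initiation cost and
#' terminal AU/GU end penalties are included. If no alignment achieves a
#' negative total, the strands are reported as non-binding with energy 0.
#'
#' @param mirna,site sequences, both 5' to 3' (the mature miRNA guide
#'   strand and the target site).
#' @param model an [energy_model()].
#' @param loop_cap per-side cap on interior-loop size in the duplex.
#' @return List with `energy` (kcal/mol, 0 when non-binding) and `pairs`, a
#'   data frame of 0-based paired positions (`mirna_pos`, `site_pos`).
#' @examples
#' duplex_energy("ACGUACGU", revcomp("ACGUACGU"))
#' @export
duplex_energy <- function(mirna, site, model = default_energy_model(),
                          loop_cap = 4L) {
  mirna <- as_nuc(mirna); site <- as_nuc(site)
  res <- c_duplex(encode_seq(mirna), encode_seq(site), unclass(model),
                  as.integer(loop_cap))
  list(energy = res$energy,
       pairs = data.frame(mirna_pos = res$i, site_pos = res$j))
}

new_rna_structure <- function(seq, pairs0, energy) {
  # pairs0: 0-based partner or -1 (engine convention)
  pairs <- ifelse(pairs0 < 0L, NA_integer_, pairs0 + 1L)
  structure(list(seq = seq, dotbracket = pairs_to_dotbracket(pairs),
                 energy = energy, pairs = pairs),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(unclass(x$seq), "\n")
  cat(sprintf("%s (%6.2f)\n", x$dotbracket, x$energy))
  invisible(x)
}

#' Dot-bracket conversions
#'
#' @param pairs integer vector of 1-based partner indices (`NA` unpaired).
#' @return `pairs_to_dotbracket()`: a dot-bracket string;
#'   `dotbracket_to_pairs()`: a partner-index vector.
#' @examples
#' dotbracket_to_pairs("((...))")
#' @export
pairs_to_dotbracket <- function(pairs) {
  db <- rep(".", length(pairs))
  paired <- which(!is.na(pairs))
  db[paired[pairs[paired] > paired]] <- "("
  db[paired[pairs[paired] < paired]] <- ")"
  paste(db, collapse = "")
}

#' @rdname pairs_to_dotbracket
#' @param dotbracket a balanced dot-bracket string (no pseudoknots).
#' @export
dotbracket_to_pairs <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  if (!all(ch %in% c(".", "(", ")")))
    stop("dot-bracket may contain only '.', '(' and ')'", call. = FALSE)
  pairs <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced brackets", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j; pairs[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced brackets", call. = FALSE)
  pairs
}

#' Free energy of a given secondary structure
#'
#' Scores an explicit structure by loop decomposition under the same
#' semantics as the folding engine: stack terms for helix-internal pairs,
#' tabulated hairpin/bulge/internal loop penalties, an affine multibranch
#' penalty, and the AU/GU end penalty on every pair side facing a loop or
#' the exterior. Useful for inspecting alternatives to the MFE structure
#' and as an independent check on the dynamic programming.
#'
#' @inheritParams mfe_fold
#' @param structure a dot-bracket string or a 1-based partner-index vector.
#' @return Energy in kcal/mol (`Inf` for structures containing an illegal
#'   pair or an undersized hairpin loop).
#' @examples
#' structure_energy("GGGAAACCC", "(((...)))")
#' @export
structure_energy <- function(seq, structure, model = default_energy_model()) {
  seq <- as_nuc(seq)
  ch <- seq_chars(seq)
  n <- length(ch)
  pairs <- if (is.character(structure)) dotbracket_to_pairs(structure)
           else as.integer(structure)
  if (length(pairs) != n)
    stop("structure length does not match sequence", call. = FALSE)

  au <- function(i, j) if (is_au_end(ch[i], ch[j])) model$au_end else 0
  lookup <- function(tab, s) if (s <= length(tab)) tab[s] else tab[length(tab)]

  # direct branches of the region (i, j) exclusive; returns matrix of pairs
  branches <- function(i, j) {
    out <- NULL
    k <- i + 1L
    while (k <= j - 1L) {
      if (!is.na(pairs[k])) {
        if (pairs[k] < k) stop("crossing pairs (pseudoknot)", call. = FALSE)
        out <- rbind(out, c(k, pairs[k]))
        k <- pairs[k] + 1L
      } else k <- k + 1L
    }
    out
  }

  opened <- which(!is.na(pairs) & pairs > seq_len(n))
  for (i in opened)
    if (!can_pair_chr(ch[i], ch[pairs[i]])) return(Inf)

  total <- 0
  # exterior loop: AU ends of top-level helices
  ext <- branches(0L, n + 1L)
  for (b in seq_len(NROW(ext))) total <- total + au(ext[b, 1], ext[b, 2])

  for (i in opened) {
    j <- pairs[i]
    br <- branches(i, j)
    h <- NROW(br)
    u <- (j - i - 1L) - if (h > 0) sum(br[, 2] - br[, 1] + 1L) else 0L
    if (h == 0L) {
      if (u < 3L) return(Inf)
      total <- total + lookup(model$hairpin, u) + au(i, j)
    } else if (h == 1L) {
      k <- br[1, 1]; l <- br[1, 2]
      s1 <- k - i - 1L; s2 <- j - l - 1L
      if (s1 == 0L && s2 == 0L) {
        total <- total + model$stack[paste0(ch[i], ch[j]), paste0(ch[k], ch[l])]
      } else if (s1 == 0L || s2 == 0L) {
        total <- total + lookup(model$bulge, s1 + s2) + au(i, j) + au(k, l)
      } else {
        total <- total + lookup(model$internal, s1 + s2) + au(i, j) + au(k, l)
      }
    } else {
      total <- total + model$ml_init + model$ml_branch * (h + 1) +
        model$ml_unpaired * u + au(i, j)
      for (b in seq_len(h)) total <- total + au(br[b, 1], br[b, 2])
    }
  }
  total
}
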