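#' Nearest-neighbor RNA energy model
#'
#' Builds the parameter set used by [mfe_fold()], [constrained_mfe()] and
#' [duplex_energy()]: a Turner-2004-style stack table (Watson-Crick and G:U
#' wobble pairs), tabulated hairpin/bulge/internal loop initiation penalties
#' extrapolated logarithmically beyond the tabulated range, an affine
#' multibranch-loop penalty, a duplex initiation constant and a terminal
#' AU/GU end penalty. All energies are free energies in kcal/mol at 37 C.
#'
#' The stack and loop tables are plain TSV files so alternative parameter
#' sets can be swapped in; the bundled defaults live in
#' `system.file("extdata", c("nn_stacks.tsv", "loop_penalties.tsv"),
#' package = "seedshift")`.
#'
#' @param stack_file TSV with columns `pair1`, `pair2`, `dG`: `pair1` is the
#'   outer pair written (5' base, partner), `pair2` the pair stacked one step
#'   inward. Must contain all 36 ordered combinations of the six legal pairs
#'   and satisfy the strand-flip symmetry `E(p1,p2) = E(flip p2, flip p1)`.
#' @param loop_file TSV with columns `type` (`hairpin`/`bulge`/`internal`),
#'   `size`, `dG`.
#' @param ml_init,ml_branch,ml_unpaired affine multibranch loop penalty:
#'   closing a multiloop costs `ml_init + ml_branch * (branches + 1) +
#'   ml_unpaired * unpaired`.
#' @param duplex_init initiation cost of forming an intermolecular duplex.
#' @param au_end penalty charged once per AU or GU pair side that faces a
#'   loop or an exterior/terminal context (helix-internal stacks are exempt).
#' @param max_loop largest bulge/internal loop size considered by the fold.
#' @return An object of class `energy_model` (list of lookup tables and
#'   constants).
#' @examples
#' m <- default_energy_model()
#' @export
energy_model <- function(stack_file, loop_file,
                         ml_init = 3.4, ml_branch = 0.4, ml_unpaired = 0.0,
                         duplex_init = 4.09, au_end = 0.5, max_loop = 30L) {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  flip <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))

  st <- read.delim(stack_file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("pair1", "pair2", "dG") %in% names(st)))
    stop("stack_file must have columns pair1, pair2, dG", call. = FALSE)
  key <- paste(st$pair1, st$pair2)
  need <- as.vector(outer(pairs, pairs, paste))
  if (!setequal(key, need) || anyDuplicated(key))
    stop("stack_file must tabulate each of the 36 pair combinations once",
         call. = FALSE)
  E <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  E[cbind(match(st$pair1, pairs), match(st$pair2, pairs))] <- st$dG
  for (p1 in pairs) for (p2 in pairs)
    if (abs(E[p1, p2] - E[flip(p2), flip(p1)]) > 1e-9)
      stop("stack table violates strand-flip symmetry at ", p1, "/", p2,
           call. = FALSE)

  # flatten to the 256-entry array indexed by encoded bases
  # (i, j, i+1, j-1); non-pairable combinations are +Inf
  base <- c("A", "C", "G", "U")
  pair_of <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% pairs) p else NA_character_
  }
  stack_flat <- rep(Inf, 256)
  for (a in 1:4) for (b in 1:4) for (c2 in 1:4) for (d in 1:4) {
    p1 <- pair_of(base[a], base[b]); p2 <- pair_of(base[c2], base[d])
    if (!is.na(p1) && !is.na(p2))
      stack_flat[(a - 1) * 64 + (b - 1) * 16 + (c2 - 1) * 4 + d] <- E[p1, p2]
  }

  lo <- read.delim(loop_file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("type", "size", "dG") %in% names(lo)))
    stop("loop_file must have columns type, size, dG", call. = FALSE)
  pick <- function(type, sizes) {
    sub <- lo[lo$type == type, ]
    v <- sub$dG[match(sizes, sub$size)]
    if (anyNA(v))
      stop("loop table missing ", type, " sizes ",
           paste(sizes[is.na(v)], collapse = ","), call. = FALSE)
    v
  }
  RT <- 0.0019872 * 310.15
  extend <- function(tab, sizes, n) {
    # logarithmic extrapolation beyond the tabulated range
    smax <- max(sizes)
    full <- rep(NA_real_, n)
    full[sizes] <- tab
    beyond <- which(is.na(full) & seq_len(n) > smax)
    full[beyond] <- tab[match(smax, sizes)] + 1.75 * RT * log(beyond / smax)
    full
  }
  hsz <- sort(lo$size[lo$type == "hairpin"])
  bsz <- sort(lo$size[lo$type == "bulge"])
  isz <- sort(lo$size[lo$type == "internal"])
  nmax <- 400L   # longest loop ever scored (hairpins are uncapped)
  hairpin <- extend(pick("hairpin", hsz), hsz, nmax)
  hairpin[seq_len(min(hsz) - 1)] <- Inf   # hairpin loops below minimum size
  bulge <- extend(pick("bulge", bsz), bsz, nmax)
  internal <- extend(pick("internal", isz), isz, nmax)
  internal[seq_len(min(isz) - 1)] <- Inf

  structure(list(stack = E, stack_flat = stack_flat,
                 hairpin = hairpin, bulge = bulge, internal = internal,
                 ml_init = ml_init, ml_branch = ml_branch,
                 ml_unpaired = ml_unpaired, duplex_init = duplex_init,
                 au_end = au_end, max_loop = as.integer(max_loop),
                 RT = RT),
            class = "energy_model")
}

#' @rdname energy_model
#' @export
default_energy_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- energy_model(
        system.file("extdata", "nn_stacks.tsv", package = "seedshift"),
        system.file("extdata", "loop_penalties.tsv", package = "seedshift"))
    }
    cache
  }
})

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> nearest-neighbor RNA parameters (37 C, kcal/mol)\n")
  cat(sprintf("  stacks: 6x6 pair table; hairpin(3)=%.2f; duplex init=%.2f; AU end=%.2f\n",
              x$hairpin[3], x$duplex_init, x$au_end))
  cat(sprintf("  multiloop: a=%.2f b=%.2f c=%.2f; max bulge/internal size=%d\n",
              x$ml_init, x$ml_branch, x$ml_unpaired, x$max_loop))
  invisible(x)
}

# TRUE for AU/UA/GU/UG pairs (the terminal-end penalty applies)
is_au_end <- function(b1, b2) {
  p <- paste0(b1, b2)
  p %in% c("AU", "UA", "GU", "UG")
}

can_pair_chr <- function(b1, b2) {
  paste0(b1, b2) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}
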