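#' RNA sequence objects
#'
#' A `nuc_sequence` is a length-one character string over the RNA alphabet
#' `A, C, G, U`, always read 5' to 3'. DNA input (`T`) is accepted and
#' normalized to `U`; case is ignored.
#'
#' @param residues character scalar; the sequence (DNA or RNA alphabet).
#' @param id optional identifier carried through reports.
#' @return An object of class `nuc_sequence` (a character scalar with an
#'   `id` attribute).
#' @examples
#' nuc_sequence("ACGTacgu", id = "demo")
#' @export
nuc_sequence <- function(residues, id = "seq") {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop("'residues' must be a single character string", call. = FALSE)
  x <- chartr("tT", "uU", residues)
  x <- toupper(x)
  if (nchar(x) == 0L) stop("empty sequence", call. = FALSE)
  bad <- gsub("[ACGU]", "", x)
  if (nchar(bad) > 0L)
    stop("invalid residues after DNA->RNA normalization: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "), call. = FALSE)
  structure(x, id = as.character(id), class = "nuc_sequence")
}

#' @export
print.nuc_sequence <- function(x, ...) {
  cat(sprintf("<nuc_sequence> %s (%d nt)\n", attr(x, "id"), nchar(x)))
  cat(unclass(x), "\n")
  invisible(x)
}

as_nuc <- function(x, id = "seq") {
  if (inherits(x, "nuc_sequence")) x else nuc_sequence(x, id = id)
}

seq_chars <- function(x) strsplit(unclass(as_nuc(x)), "")[[1]]

#' Reverse complement of an RNA sequence
#'
#' @param x a `nuc_sequence` or character scalar (DNA accepted).
#' @return A `nuc_sequence` with the reverse complement (RNA alphabet).
#' @examples
#' revcomp("GGAUC")
#' @export
revcomp <- function(x) {
  x <- as_nuc(x)
  rc <- paste(rev(strsplit(chartr("ACGU", "UGCA", unclass(x)), "")[[1]]),
              collapse = "")
  nuc_sequence(rc, id = paste0(attr(x, "id"), "_rc"))
}

# integer encoding used by the folding engine: A=0, C=1, G=2, U=3
encode_seq <- function(x) {
  match(seq_chars(x), c("A", "C", "G", "U")) - 1L
}

#' A SNP within a target sequence window
#'
#' Positions are 0-based indices into the window (not genomic coordinates);
#' an optional `genomic_offset` can be carried for reporting.
#'
#' @param snp_id identifier, e.g. `"rs4937333"`.
#' @param position 0-based position of the variant in the window.
#' @param ref_allele,alt_allele single residues (DNA accepted, normalized).
#' @param window optional `nuc_sequence`; when given, the residue at
#'   `position` must equal `ref_allele`.
#' @param genomic_offset optional integer added to positions in reports.
#' @return An object of class `snp_variant`.
#' @export
snp_variant <- function(snp_id, position, ref_allele, alt_allele,
                        window = NULL, genomic_offset = NA_integer_) {
  ref <- unclass(nuc_sequence(ref_allele))
  alt <- unclass(nuc_sequence(alt_allele))
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("alleles must be single residues", call. = FALSE)
  if (ref == alt) stop("ref and alt alleles are identical", call. = FALSE)
  position <- as.integer(position)
  if (!is.null(window)) {
    window <- as_nuc(window)
    if (position < 0L || position >= nchar(window))
      stop("SNP position outside the window", call. = FALSE)
    if (substr(unclass(window), position + 1L, position + 1L) != ref)
      stop("window residue at SNP position does not match ref_allele",
           call. = FALSE)
  }
  structure(list(snp_id = as.character(snp_id), position = position,
                 ref_allele = ref, alt_allele = alt,
                 genomic_offset = genomic_offset),
            class = "snp_variant")
}

#' Apply the alternate allele of a SNP to a window
#'
#' @param window a `nuc_sequence` carrying the reference allele.
#' @param snp a [snp_variant()].
#' @return The window with the alt residue substituted at the SNP position.
#' @export
apply_alt_allele <- function(window, snp) {
  window <- as_nuc(window)
  if (substr(unclass(window), snp$position + 1L, snp$position + 1L) !=
      snp$ref_allele)
    stop("window does not carry the ref allele at the SNP position",
         call. = FALSE)
  s <- seq_chars(window)
  s[snp$position + 1L] <- snp$alt_allele
  nuc_sequence(paste(s, collapse = ""),
               id = paste0(attr(window, "id"), "_", snp$alt_allele))
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()]; sequences are
#' normalized to the RNA alphabet.
#'
#' @param path FASTA file (DNA or RNA).
#' @return A named list of `nuc_sequence` objects.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- lapply(seq_along(ss), function(i)
    nuc_sequence(as.character(ss[[i]]), id = names(ss)[i]))
  names(out) <- names(ss)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs a list of `nuc_sequence` objects (or character strings).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(seqs, path) {
  seqs <- lapply(seqs, as_nuc)
  nm <- vapply(seqs, function(s) attr(s, "id"), character(1))
  ss <- Biostrings::BStringSet(setNames(vapply(seqs, unclass, character(1)), nm))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
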