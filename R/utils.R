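#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap keep
#'   list_rbind
NULL

#' Translate a coding DNA sequence
#'
#' Thin wrapper around [Biostrings::translate()] that accepts a plain
#' character string and returns a plain character string. Translation stops
#' at the end of the sequence; internal stop codons are rendered as `*`.
#'
#' @param dna A single DNA string whose length is a multiple of 3 (a trailing
#'   remainder of 1-2 nt is dropped with a warning only if `partial = TRUE`).
#' @param partial Allow a trailing partial codon (silently dropped).
#' @return A single amino-acid string.
#' @export
translate_dna <- function(dna, partial = FALSE) {
  stopifnot(is.character(dna), length(dna) == 1L)
  n <- nchar(dna)
  if (n %% 3L != 0L) {
    if (!partial) abort("sequence length is not a multiple of 3")
    dna <- substr(dna, 1L, n - n %% 3L)
  }
  if (nchar(dna) == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(dna),
    if.fuzzy.codon = "solve", no.init.codon = TRUE
  ))
}

#' Reverse complement of a DNA string
#' @param dna A single DNA string (IUPAC codes supported).
#' @return The reverse complement, as a character string.
#' @export
revcomp <- function(dna) {
  intToUtf8(rev(utf8ToInt(
    chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
           "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", dna)
  )))
}

# Random DNA of length n from an RNG already seeded by the caller.
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Hamming distance between equal-length strings (no alignment).
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (a == b) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Longest common prefix length of two strings.
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# Split a codon string into a character vector of codons.
codons_of <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character())
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Locate inserted residues between two protein sequences
#'
#' Compares a reference and an alternative protein and, when the alternative
#' is longer, reports the inserted stretch by maximal common prefix/suffix
#' trimming. Used, e.g., to recover the seven stem residues (PTTGPTS) added
#' by the 21-bp exon-9 insertion.
#'
#' @param ref,alt Protein strings; `alt` at least as long as `ref`.
#' @return The inserted peptide (possibly `""`).
#' @export
peptide_insertion <- function(ref, alt) {
  if (nchar(alt) < nchar(ref)) abort("`alt` must not be shorter than `ref`")
  p <- lcp_len(ref, alt)
  rr <- paste(rev(strsplit(ref, "")[[1]]), collapse = "")
  aa <- paste(rev(strsplit(alt, "")[[1]]), collapse = "")
  s <- lcp_len(rr, aa)
  # prefix and suffix may overlap on the shorter sequence
  s <- min(s, nchar(ref) - p, nchar(alt) - p)
  substr(alt, p + 1L, nchar(alt) - s)
}
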