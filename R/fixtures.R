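#' Canonical synthetic LILRB1/LILRB2 fixtures
#'
#' The package ships no real allele sequences; instead it constructs, in
#' code, a deterministic synthetic genomic allele that satisfies every
#' structural statement of the canonical LILRB1 gene model: 16 exons, 14 of
#' them encoding the mature mRNA, start codon in exon 3 (after a 30-bp
#' 5' UTR), stop codon 147 bp into exon 16, D1-D4 on exons 5-8, stem on
#' exons 9-10, TM on exon 11, cytoplasmic tail on exons 12-16 with four
#' ITIM motifs of which exactly one lies in exon 15 (126 bp). Intron 9 ends
#' in `GCA` so that a 3-bp alternative 3' splice site at exon 10 inserts an
#' alanine codon, and intron 14 ends in `CAG` so the corresponding event at
#' exon 15 inserts a glutamine; the first five codons of exon 10 are fixed
#' so that 1- or 2-bp micro-insertions at its acceptor put a stop codon
#' inside exon 10 in the shifted frame, as observed for the premature-stop
#' isoforms. The first 30 bp of intron 15 carry no in-frame stop, so a
#' 30-bp partial intron-15 retention (exon 15 of 156 bp) stays translatable.
#'
#' @name lilr_fixtures
NULL

# Run expr with a private RNG state, restoring the caller's state.
with_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Canonical exon lengths (bp), genomic exon numbering 1..16.
LILRB1_EXON_LENGTHS <- c(
  100L, 80L, 78L, 36L, 294L, 294L, 294L, 294L,
  63L, 51L, 108L, 69L, 90L, 90L, 126L, 447L
)

# Amino acids available for random protein design (20 standard).
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

ITIM_MOTIF <- "SEYATL"

# Residue positions (codon numbers) where the four ITIMs are planted:
# exons 12, 13, 14 and 15 of the canonical model.
ITIM_SITES <- c(500L, 525L, 555L, 590L)

# Exon-10 first five codons, fixed at the nucleotide level so that +1/+2
# acceptor micro-insertions hit a stop codon inside exon 10:
#   in-frame  : CTA ATG AAC AAT GAC  (L M N N D)
#   +1 frame  : ACT AAT GAA CAA TGA* (micro-insertion of "A")
#   +2 frame  : CAC TAA*             (micro-insertion of "CA")
EXON10_HEAD_CODONS <- c("CTA", "ATG", "AAC", "AAT", "GAC")

#' Canonical LILRB1 gene model
#'
#' @param exon9_insert_len Extra length of exon 9 (21 for insert-bearing
#'   alleles, 0 otherwise).
#' @return A `gene_model` for the synthetic canonical LILRB1 allele.
#' @export
lilrb1_model <- function(exon9_insert_len = 0L) {
  lens <- LILRB1_EXON_LENGTHS
  lens[9] <- lens[9] + as.integer(exon9_insert_len)
  build_canonical_model(
    "LILRB1", lens,
    first_exon = 1L, first_mrna_exon = 3L, start_codon_exon = 3L,
    utr5_len = 30L, coding_prefix_len = 147L,
    intron_lengths = rep(100L, 15L)
  )
}

#' Canonical LILRB2 gene model
#'
#' Exon 1 and intron 1 of LILRB2 cannot be resolved in public assemblies,
#' so the model starts at exon 2 (genomic numbering retained).
#'
#' @return A `gene_model` starting at exon 2.
#' @export
lilrb2_model <- function() {
  build_canonical_model(
    "LILRB2", LILRB1_EXON_LENGTHS[-1],
    first_exon = 2L, first_mrna_exon = 3L, start_codon_exon = 3L,
    utr5_len = 30L, coding_prefix_len = 147L,
    intron_lengths = rep(100L, 14L)
  )
}

# Design the canonical 668-codon CDS (667 aa + stop) as codon strings.
design_cds_codons <- function() {
  n_codon <- 668L
  aa <- sample(AA_ALPHABET, n_codon - 1L, replace = TRUE)
  aa[1] <- "M"
  for (p in ITIM_SITES) {
    aa[p:(p + 5L)] <- strsplit(ITIM_MOTIF, "")[[1]]
  }
  prot <- paste(aa, collapse = "")
  # scrub accidental ITIM matches outside the four planted sites
  repeat {
    hits <- itim_positions(prot)
    extra <- setdiff(hits, ITIM_SITES)
    if (length(extra) == 0L) break
    substr(prot, extra[1] + 2L, extra[1] + 2L) <- "A" # remove the Y
  }
  aa <- strsplit(prot, "")[[1]]
  codon_table <- Biostrings::GENETIC_CODE
  codons <- map_chr(aa, function(a) {
    opts <- names(codon_table)[codon_table == a]
    opts[sample.int(length(opts), 1L)]
  })
  # fixed nucleotide-level constraints
  codons[1] <- "ATG"
  codons[442:446] <- EXON10_HEAD_CODONS
  c(codons, "TGA")
}

# One intron: GT ... AG with optional fixed tail (last bases) and head.
design_intron <- function(len, tail3 = NULL, stop_free_head = 0L) {
  body <- random_dna(len)
  substr(body, 1L, 2L) <- "GT"
  substr(body, len - 1L, len) <- "AG"
  if (stop_free_head > 0L) {
    # positions 4..stop_free_head read in frame after a retention event;
    # keep them stop-free so partial retention stays translatable
    k <- (stop_free_head - 3L) %/% 3L
    head_codons <- sample(NON_STOP_CODONS, k + 1L, replace = TRUE)
    head <- paste0("GT", sample(DNA_BASES, 1L),
                   paste(head_codons[seq_len(k)], collapse = ""))
    substr(body, 1L, nchar(head)) <- head
  }
  if (!is.null(tail3)) {
    substr(body, len - nchar(tail3) + 1L, len) <- tail3
  }
  body
}

#' Build the canonical synthetic LILRB1 allele fixture
#'
#' Deterministically constructs the canonical genomic allele, its gene
#' model, CDS and protein. All randomness comes from `seed`; calling twice
#' with the same seed is byte-identical.
#'
#' @param seed Integer seed for the private RNG (default gives the
#'   package's reference fixture).
#' @return A list with elements `model` (gene_model with ITIM counts),
#'   `genomic`, `cds`, `protein`, `transcript` and `exon_seqs`/`intron_seqs`.
#' @export
lilrb1_fixture <- function(seed = 715001L) {
  with_rng(seed, {
    model <- lilrb1_model()
    codons <- design_cds_codons()
    cds <- paste(codons, collapse = "")

    ex <- model$exons
    exon_seqs <- character(nrow(ex))
    cum <- 0L
    for (i in seq_len(nrow(ex))) {
      clen <- ex$coding_len[i]
      if (clen == 0L) {
        exon_seqs[i] <- random_dna(ex$length[i])
      } else {
        coding_part <- substr(cds, cum + 1L, cum + clen)
        utr5 <- if (ex$exon[i] == model$start_codon_exon) {
          random_dna(model$utr5_len)
        } else ""
        utr3 <- if (clen < ex$length[i] - nchar(utr5)) {
          random_dna(ex$length[i] - nchar(utr5) - clen)
        } else ""
        exon_seqs[i] <- paste0(utr5, coding_part, utr3)
        cum <- cum + clen
      }
    }

    nint <- nrow(model$introns)
    intron_seqs <- character(nint)
    for (i in seq_len(nint)) {
      len <- model$introns$length[i]
      intron_seqs[i] <- switch(
        as.character(model$introns$intron[i]),
        "9"  = design_intron(len, tail3 = "GCA"),   # alt-3'ss: Ala codon
        "14" = design_intron(len, tail3 = "CAG"),   # alt-3'ss: Gln codon
        "15" = design_intron(len, stop_free_head = 30L), # 30-bp retention
        design_intron(len)
      )
    }

    genomic <- assemble_genomic(model, exon_seqs, intron_seqs)
    model <- annotate_itims(model, genomic)
    list(
      model = model,
      genomic = genomic,
      cds = cds,
      protein = translate_dna(cds),
      transcript = extract_transcript(model, genomic),
      exon_seqs = exon_seqs,
      intron_seqs = intron_seqs
    )
  })
}

# 21-bp in-frame insertion carried by the exon-9 insert alleles; encodes
# the stem extension PTTGPTS.
EXON9_INSERT_SEQ <- "CCAACCACCGGACCCACCTCG"

# Offset (bp from exon-9 start) after which the insert is placed; a codon
# boundary, so the insertion is in frame.
EXON9_INSERT_OFFSET <- 21L
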